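---
title: "Models and methods for signaling-peptide family diversification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for signaling-peptide family diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pepfam` analyzes how short secreted signaling peptides — exemplified by the
plant CLE family, whose ~100-residue precursors are cleaved into 12-residue
dodecapeptides — diversify after gene duplication. This vignette is the
package's own account of its models, assumptions and numerical choices. It
states no empirical result that the test suite and `scripts/acceptance.R` do
not themselves compute.

```{r setup, eval = FALSE}
library(pepfam)
```

## Why a network, not an alignment

Short, fast-evolving peptide precursors align poorly: outside the conserved
dodecapeptide almost every column is saturated, so tree inference from a
multiple alignment is unreliable. The package instead works from an
all-by-all similarity network. `align_pair()` computes exact Smith–Waterman
local alignment (BLOSUM62, affine gap open 11 / extend 1 — the familiar
protein-search defaults), and `score_to_weight()` maps scores through a
Karlin–Altschul-style transform,

$$ w = \max\left(0,\; -\log_{10}\!\big(K\,m\,n\,e^{-\lambda S}\big)\right), $$

with $\lambda = 0.267$, $K = 0.041$ (the ungapped BLOSUM62 constants), $m$
the query length and $n$ the total residue count of the gene set. The
transform exists to make weights comparable across sequence lengths while
preserving strict monotonicity in the score; the absolute E-value calibration
is immaterial for the downstream graph algorithms. Using exact alignment
rather than a heuristic seeded search makes the whole pipeline deterministic
and testable against a brute-force dynamic-programming oracle.

`prune_top_k()` keeps an edge when it ranks in the top *k* (default 500) of
*either* endpoint. Union semantics — rather than requiring both endpoints to
rank the edge — biases the pruned graph toward staying connected, which
matters for the random walks that follow; the choice is stated here because
either convention is defensible.

## Embedding and projection

`random_walks()` performs second-order biased walks (return bias $p$,
in–out bias $q$; both default to 1, i.e. first-order weight-proportional
transitions, since nothing in the analysis requires asymmetric exploration).
Instead of training a skip-gram by stochastic gradient descent,
`embed_walks()` uses its known closed-form equivalent: symmetric window
co-occurrence counts, the shifted positive pointwise-mutual-information
transform, and a truncated SVD with $U\sqrt{\Sigma}$ output. The closed form
is deterministic given the walk corpus (component signs are fixed by
convention), so embedding tests can assert exact properties — e.g. that
permuting the corpus leaves the Gram matrix unchanged.

Walk defaults are desk-scale (length 80, 20 walks per node, window 10);
`walk_config(paper_scale = TRUE)` switches to the heavy preset (200 / 600 /
100) appropriate for genome-scale families. The desk defaults were chosen
once so that the full test suite runs in minutes; they are ample for the
family sizes (tens to low hundreds of genes) the synthetic generator
produces.

`project_2d()` is a compact potential-of-heat (PHATE-style) projection:
adaptive-bandwidth kernel $\exp(-(d/\sigma_k)^\alpha)$ with $\alpha = 2$ and
$\sigma_k$ the distance to the 5th neighbor, row-normalized to a Markov
matrix, $t$-step diffusion with $t$ chosen at the knee of the von Neumann
entropy curve, log-potential distances, classical MDS. Landmarking and other
large-$n$ machinery are deliberately omitted; the graphs here are small.

## Multi-resolution hierarchy

`multires_communities()` optimizes the constant Potts model objective
$\sum_c \big[w_{in}(c) - \gamma\, n_c (n_c - 1)/2\big]$ with the Leiden
algorithm at an ascending resolution ladder (default: six values spaced
geometrically over the observed edge-weight scale). CPM was chosen over
modularity because its resolution parameter has a direct interpretation as a
within-community density threshold, which is the standard choice for
resolution sweeps. Each resolution is run with ten seeded restarts and the
best CPM quality kept; on every graph small enough to enumerate
(≤ 8 nodes) the result is checked against the exhaustive optimum in the
test suite.

`reconcile_tree()` turns the (possibly non-nested) partitions into a
strictly nested hierarchy minimizing the number of per-gene, per-layer
membership changes. The algorithm alternates (a) plurality-containment
lifting of cluster parents from the leaf assignment and (b) reassignment of
each gene to the leaf path with the fewest disagreements, until the cost
stops improving. On two-layer instances with up to seven genes the result
matches a brute-force search over all leaf assignments and parent maps.

Two corrections acknowledge that community detection over-fragments leaves:

- `prune_sisters_rf()` tests each pair of sister leaves with a
  random-forest classifier on one-hot dodecapeptide positions ("12
  categorical features"), compares the out-of-bag accuracy with a null from
  label permutations (default 199), and merges pairs whose accuracy does not
  exceed the $1-\alpha$ null quantile. Out-of-bag accuracy is used as the
  out-of-sample estimate rather than explicit cross-validation folds: it is
  the canonical random-forest estimate, requires one forest per test instead
  of five, and keeps the 200-pair calibration experiment within minutes.
  The p-value convention is $(1 + \#\{null \ge obs\})/(n_{perm}+1)$, which
  can never return zero. $\alpha = 1$ is degenerate and merges
  unconditionally.
- `resolve_polytomy_entropy()` resolves nodes with $m \ge 3$ children into
  a binary subtree minimizing the summed member-weighted positional Shannon
  entropy of each internal node,
  $\text{cost}(v) = n_v \sum_{p=1}^{12} H_p(v)$. For $m \le 6$ the optimum
  is found by dynamic programming over child subsets; beyond that a greedy
  agglomeration (each merge minimizes the entropy increase) is used. Greedy
  is *not* guaranteed optimal — the tests verify only that it never beats
  the optimum — which is why the exhaustive route is the default wherever
  it is feasible. Ties break deterministically by child id.

## The Potts model and mutational effects

The dodecapeptide collection is treated as a gapless 12-column alignment
over the strict 20-letter alphabet. `fit_potts()` maximizes the weighted,
L2-regularized pseudolikelihood; the objective is convex, so optimization
starts from zero and uses full-batch L-BFGS-B with a relative convergence
tolerance of $10^{-6}$. Couplings are parameterized symmetrically
($J_{ij} = J_{ji}^\top$, zero diagonal blocks), which is equivalent to
averaging the two conditional estimates of each block. Defaults follow the
common plmDCA conventions: reweighting threshold $\theta = 0.8$ (each
sequence weighted by the reciprocal of its ≥ 80%-identity neighborhood
size), $\lambda_h = 0.01A$ and $\lambda_J = 0.01A(L-1)$.

**Sign convention.** Energies are defined so that *higher* statistical
energy means *more probable*: $E(s) = \sum_i h_i(s_i) + \sum_{i<j}
J_{ij}(s_i, s_j)$ and a deleterious substitution has a *negative* effect
$\Delta E = E(\text{mut}) - E(\text{wt})$. This is stated prominently
because both orientations appear in the literature.

`mutational_effect()` computes $\Delta E$ incrementally in $O(L)$ and is
tested to equal the full-energy recomputation; wild-type substitutions are
exactly zero by construction. `coupling_map()` summarizes each coupling
block by its Frobenius norm in the zero-sum gauge and applies the average
product correction, the standard background correction that exactly
annihilates rank-one (site-entropy) structure.

`residualize_blosum()` regresses $\Delta E$ on the BLOSUM62 score of each
substitution and returns residuals: what remains after removing generic
amino-acid exchangeability. `sneath_correlation()` then correlates the
residuals with a pairwise biochemical dissimilarity of the (wild-type,
mutant) residues. The literature table of Sneath's dissimilarity is not
redistributed here; the packaged index is *constructed* at run time from
five physicochemical property scales in the AAindex collection shipped with
seqinr (Kyte–Doolittle hydropathy, Grantham polarity and volume,
isoelectric point, bulkiness; z-scored, Euclidean, rescaled to [0, 1]).
`aa_dissimilarity()` documents this provenance; any user-supplied 20×20
table can be passed instead. `conservation_score()` aggregates site-level
values as the proportion above 0.6, the conventional threshold for
language-model conservation profiles.

## Burden versus duplication age

`synonymous_distance()` implements Nei–Gojobori (1986) counting: per-codon
synonymous site fractions averaged between the two sequences,
pathway-averaged synonymous differences for multi-hit codons (pathways
through stop codons are excluded; if every pathway is inviable the counts
fall back to ignoring viability rather than dropping the codon), and the
Jukes–Cantor correction $d_S = -\tfrac34 \ln(1 - \tfrac43 p_s)$, with a
saturation flag when $p_s \ge 3/4$. It is implemented in the package rather
than delegated because the installed phylogenetics stacks provide Li-style
counting, not the pathway-enumeration variant pinned down here; the tests
check every one- and two-hit codon pair against exhaustive enumeration.

`burden_score()` accumulates $\max(0, -\Delta E)$ over positions where a
gene's motif differs from its reference — only deleterious contributions
count, with no magnitude threshold. The reference is the clade
column-majority consensus (a configurable stand-in for the unobservable
ancestral sequence). `paralog_burden_test()` fits
`burden ~ dS + is_paralog` by least squares and permutes the paralog flag
*within dS quartile strata*, so that duplication age cannot masquerade as a
paralog effect; single-class strata are dropped with a warning and the
p-value follows the add-one permutation convention.

## Three-population analysis

Pooled sequencing of three phenotype classes — segregating, fixed WT-like,
fixed mutant-like — identifies genes whose disruption tracks the phenotype.
The per-gene mutational index is deliberately simple: over a gene's
disruptive-consequence variants (default classes: frameshift, stop gain,
motif-disrupting), `mi_mut` is the maximum mutant-pool allele fraction,
`mi_wt` the WT-pool fraction of that same variant, and segregating support
requires the segregating-pool fraction to lie strictly inside
$(\tau_{lo}, \tau_{hi}) = (0.2, 0.8)$. A candidate must satisfy
`mi_mut >= 0.8`, `mi_wt <= 0.2` and segregating support — the "bottom
right" of the index plane. Off-target variants are scored but never called.
The max-variant rule and the thresholds are explicit package choices: the
index geometry only requires that causal knockouts be fixed in the mutant
pool, absent in the WT pool, and segregating in between.

`promoter_cluster_test()` asks whether candidates cluster in the promoter
similarity network: the statistic is their mean pairwise similarity (absent
edges count zero) against a null of uniformly resampled same-size node
sets. `filter_expression_samples()` applies the two standard expression QC
rules: drop samples at ≤ 50% uniquely mapped reads, then drop replicates
whose median Spearman correlation (log2 TPM + 1) with their group is
≤ 0.75.

## Promoter similarity and paralog groups

Conserved noncoding blocks shared by paralog pairs erode asymmetrically —
each copy can retain a different fragment of the ancestral block. Alignment-
based conservation calling is out of scope, so `promoter_similarity()` uses
the containment Jaccard of canonical 12-mers,
$|K_a \cap K_b| / \min(|K_a|, |K_b|)$: containment (unlike plain Jaccard)
stays high when one promoter keeps only a fragment of the shared block, and
canonical k-mers make the measure strand-aware. Connected components of the
promoter network at similarity ≥ 0.5 seed paralog groups;
`propagate_labels()` extends them over the embedding kNN graph by
synchronous, clamped weighted-majority voting (synchronous for determinism;
ties leave a node unlabeled for the round and break lexicographically only
at termination).

## What the synthetic data does and does not emulate

`generate_family()` simulates a balanced binary clade tree. On each branch
the 12-residue motif accumulates Binomial$(12, \mu)$ substitutions with
BLOSUM62-biased replacements ($\mu$ = `motif_divergence`, default 0.15);
within a clade each gene mutates at $\mu/4$. The non-motif "variable"
segment evolves along the same tree at $3\mu$ — faster than the motif, as in
real precursors, but still carrying clade signal; a variable region drawn
independently per gene would make clade recovery from full-precursor
similarity impossible for any method, which is not the regime the analysis
targets. The signal peptide is a fixed hydrophobic-rich prefix (no
signal-prediction emulation). CDSs descend from a per-clade ancestral
reverse translation with codon-level recoding only at changed residues plus
a 5% per-synonymous-site drift, so synonymous distances reflect shared
descent. Duplication events copy a parent gene, plant synonymous changes at
a 10% rate (recorded as `ds_truth`), and erode the promoter block
complementarily: the parent loses the final `erosion_asymmetry` fraction,
the duplicate the initial fraction, so 0.5 gives disjoint retained halves
that tile the block.

Three-pool experiments place causal variants at pool frequencies
(1, 0, ~0.5) and non-causal variants at one phenotype-independent frequency
per gene; observed fractions are binomial draws at the configured depth.
There is no read-mapping error model, no linkage between targets, and no
indel realism in promoters beyond block replacement — variant calling and
alignment are out of scope, so passing tests say nothing about those steps
on real data. Similarly, the family generator produces clean clade
structure without horizontal exchange, gene loss or rate heterogeneity
across lineages; recovery statistics on it are upper bounds, not field
estimates.

Problem sizes used by the tests and the acceptance script — 5,000 sampled
motifs for coupling recovery, the 6 × 20-gene default family, 50 three-pool
experiments at depth 100, 200 calibration pairs, 400 null replicates — were
fixed once as desk-scale study conditions commensurate with the family
sizes the generator emulates.

## Numerical choices and degenerate inputs

- Permutation p-values throughout use $(1 + \#extreme)/(n_{perm} + 1)$ and
  never return 0.
- The L-BFGS-B convergence tolerance is $10^{-6}$ relative objective
  change; zero initialization is exact for the convex pseudolikelihood.
- `score_to_weight()` clips at 0; zero-weight edges (E ≥ 1) are never
  stored.
- Ties: top-k pruning breaks by lexicographic partner id; polytomy merges
  by child id; label-propagation votes lexicographically at termination;
  SVD component signs are fixed by the largest-magnitude loading.
- Degenerate inputs fail loudly: empty partitions, graphs or variant
  tables, promoters shorter than k, ragged alignments, saturated dS pairs
  (flagged, not silently corrected), single-class permutation strata
  (dropped with a warning; error if none remain).
- `embed_walks()` reduces `dims` to the vocabulary size with a warning;
  `project_2d()` pads degenerate MDS output.

## Known limitations

- The Potts fit is pseudolikelihood-based; for very small effective sample
  sizes (`Neff` in the single digits) fields dominate and couplings shrink
  to the prior — `glance()` reports `neff` so users can judge.
- The biochemical dissimilarity index is a documented stand-in, not
  Sneath's published table; correlation *magnitudes* against it are not
  comparable across software that uses the original.
- Tree reconciliation minimizes a label-disagreement objective with local
  search; optimality is verified exhaustively only at small n.
- The three-population model assumes independent targets; linked loci would
  require a genetic map, which is out of scope.
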