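# Seeded synthetic peptide families with planted ground truth. The generators
# emulate the study conditions every downstream stage is tested against: a
# gene family with nested clades whose divergence is dominated by a 12-residue
# motif, paralog pairs with asymmetric erosion of a shared conserved promoter
# block, motifs drawn from a fielded/coupled Potts distribution, and pooled
# CRISPR variant tables from three phenotype populations.

# Fixed hydrophobic-rich signal-peptide prefix (no signal-prediction emulation)
SIGNAL_PEPTIDE <- "MKTSMILFLFLALLLVASA"

#' Configuration for the synthetic family generator
#'
#' @param n_clades number of clades (leaves of a balanced binary clade tree).
#' @param genes_per_clade genes simulated per clade.
#' @param motif_divergence per-site substitution probability applied to the
#'   12-residue motif on each clade-tree branch. Within-clade per-gene rate is
#'   `motif_divergence / 4`; the non-motif variable segment evolves at three
#'   times the motif rate.
#' @param variable_length length of the variable precursor segment.
#' @param promoter_length promoter length in bases.
#' @param cns_block integer `c(start, length)` of the conserved noncoding
#'   block within the promoter (1-based start).
#' @param erosion_asymmetry fraction of the block lost per paralog side:
#'   the parent loses this fraction from the block's end, the duplicate from
#'   its start, so at 0.5 the retained halves are disjoint and tile the block.
#' @param duplication_events number of paralog-creating duplications.
#' @param seed integer seed; mandatory for reproducibility.
#' @return a validated `family_sim_config` list.
#' @export
family_sim_config <- function(n_clades = 6, genes_per_clade = 20,
                              motif_divergence = 0.15, variable_length = 40,
                              promoter_length = 1000,
                              cns_block = c(start = 301, length = 200),
                              erosion_asymmetry = 0.5,
                              duplication_events = 5, seed = 1) {
  cfg <- list(
    n_clades = check_count(n_clades, "n_clades"),
    genes_per_clade = check_count(genes_per_clade, "genes_per_clade"),
    motif_divergence = check_rate(motif_divergence, "motif_divergence"),
    variable_length = check_count(variable_length, "variable_length"),
    promoter_length = check_count(promoter_length, "promoter_length"),
    cns_block = c(
      start = check_count(cns_block[[1]], "cns_block start"),
      length = check_count(cns_block[[2]], "cns_block length")
    ),
    erosion_asymmetry = check_rate(erosion_asymmetry, "erosion_asymmetry"),
    duplication_events = check_count(duplication_events, "duplication_events",
      min = 0L
    ),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$cns_block[["start"]] + cfg$cns_block[["length"]] - 1L >
    cfg$promoter_length) {
    abort("cns_block must lie within the promoter.")
  }
  structure(cfg, class = "family_sim_config")
}

# BLOSUM62-biased residue substitution: proposal probability proportional to
# exp(score / 2) over the 19 alternatives, so divergence resembles real
# amino-acid exchange.
substitute_residues <- function(chars, sites, blosum) {
  for (s in sites) {
    cur <- chars[s]
    alt <- setdiff(AA_ALPHABET, cur)
    p <- exp(blosum[cur, alt] / 2)
    chars[s] <- sample(alt, 1L, prob = p / sum(p))
  }
  chars
}

mutate_string <- function(s, rate, blosum) {
  ch <- seq_to_chars(s)
  k <- rbinom(1L, length(ch), rate)
  if (k > 0L) {
    ch <- substitute_residues(ch, sample.int(length(ch), k), blosum)
  }
  chars_to_seq(ch)
}

mutate_dna <- function(s, rate) {
  ch <- seq_to_chars(s)
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  chars_to_seq(ch)
}

# Derive a CDS from an ancestral CDS: recode only the codons whose amino
# acid changed (random synonymous codon for the new residue), preserving
# codon ancestry elsewhere so synonymous distances reflect shared descent.
derive_cds <- function(ancestor_cds, ancestor_aa, target_aa) {
  if (ancestor_aa == target_aa) {
    return(ancestor_cds)
  }
  a <- seq_to_chars(ancestor_aa)
  b <- seq_to_chars(target_aa)
  codons <- substring(
    ancestor_cds, seq(1L, nchar(ancestor_cds), 3L),
    seq(3L, nchar(ancestor_cds), 3L)
  )
  tab <- codons_for_aa()
  for (i in which(a != b)) {
    opts <- tab[[b[i]]]
    codons[i] <- opts[sample.int(length(opts), 1L)]
  }
  paste(codons, collapse = "")
}

# Evolve ancestor sequences down a balanced binary tree; returns one
# (motif, variable) pair per clade.
evolve_clades <- function(n_clades, motif_rate, var_rate, variable_length,
                          blosum) {
  depth <- max(1L, ceiling(log2(n_clades)))
  nodes <- list(list(
    motif = random_aa(12L),
    variable = random_aa(variable_length)
  ))
  for (d in seq_len(depth)) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      for (b in 1:2) {
        nxt[[2L * (i - 1L) + b]] <- list(
          motif = mutate_string(nodes[[i]]$motif, motif_rate, blosum),
          variable = mutate_string(nodes[[i]]$variable, var_rate, blosum)
        )
      }
    }
    nodes <- nxt
  }
  nodes[seq_len(n_clades)]
}

# Apply k synonymous codon changes to a CDS; returns list(cds, n_changes,
# syn_sites). Synonymous site count follows the Nei-Gojobori fractional
# convention so ds_truth = n_changes / syn_sites is a usable oracle.
plant_synonymous <- function(cds, rate = 0.1) {
  n <- nchar(cds)
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  ng <- ng_site_table()
  syn_sites <- sum(ng$S[codons])
  k <- rbinom(1L, round(syn_sites), rate)
  tab <- codons_for_aa()
  gc <- genetic_code()
  replaceable <- which(vapply(codons, function(cd) {
    length(tab[[gc[[cd]]]]) > 1L
  }, logical(1)))
  k <- min(k, length(replaceable))
  if (k > 0L) {
    for (i in sample(replaceable, k)) {
      opts <- setdiff(tab[[gc[[codons[i]]]]], codons[i])
      codons[i] <- sample(opts, 1L)
    }
  }
  list(
    cds = paste(codons, collapse = ""),
    ds_truth = if (syn_sites > 0) k / syn_sites else 0
  )
}

#' Generate a synthetic peptide gene family with planted truth
#'
#' Simulates a balanced binary clade tree whose branches accumulate
#' BLOSUM62-biased substitutions in the 12-residue motif (and, faster, in the
#' variable segment), populates each clade with genes, reverse-translates
#' precursors into CDSs, draws random promoters, and creates paralog pairs by
#' duplication with complementary erosion of a shared conserved promoter
#' block. Deterministic for a fixed seed.
#'
#' @param config a [family_sim_config()].
#' @return list with `genes` (tibble: gene_id, species, precursor,
#'   dodecapeptide, cds, promoter, clade_truth, paralog_group_truth) and
#'   `truth` (list: clade_partition tibble, paralog_pairs tibble with planted
#'   dS and retained-block coordinates, causal_genes, generating_model).
#' @export
generate_family <- function(config) {
  if (!inherits(config, "family_sim_config")) {
    config <- do.call(family_sim_config, as.list(config))
  }
  withr::with_seed(config$seed, generate_family_impl(config))
}

generate_family_impl <- function(cfg) {
  blosum <- blosum62_matrix()[AA_ALPHABET, AA_ALPHABET]
  clades <- evolve_clades(
    cfg$n_clades, cfg$motif_divergence,
    min(1, 3 * cfg$motif_divergence), cfg$variable_length, blosum
  )
  within_rate <- cfg$motif_divergence / 4
  rows <- list()
  for (cl in seq_len(cfg$n_clades)) {
    clade_prec <- paste0(
      SIGNAL_PEPTIDE, clades[[cl]]$variable, clades[[cl]]$motif
    )
    clade_cds <- reverse_translate(clade_prec)
    for (g in seq_len(cfg$genes_per_clade)) {
      motif <- mutate_string(clades[[cl]]$motif, within_rate, blosum)
      variable <- mutate_string(
        clades[[cl]]$variable, min(1, 3 * within_rate), blosum
      )
      precursor <- paste0(SIGNAL_PEPTIDE, variable, motif)
      cds <- derive_cds(clade_cds, clade_prec, precursor)
      cds <- plant_synonymous(cds, rate = 0.05)$cds
      rows[[length(rows) + 1L]] <- tibble(
        gene_id = sprintf("C%02dG%03d", cl, g),
        species = sprintf("sp%02d", g),
        precursor = precursor,
        dodecapeptide = motif,
        cds = cds,
        promoter = random_dna(cfg$promoter_length),
        clade_truth = sprintf("clade%02d", cl),
        paralog_group_truth = NA_character_
      )
    }
  }
  genes <- dplyr::bind_rows(rows)

  # paralogs by duplication with complementary promoter-block erosion
  bs <- cfg$cns_block[["start"]]
  bl <- cfg$cns_block[["length"]]
  lost <- floor(cfg$erosion_asymmetry * bl)
  pairs <- list()
  if (cfg$duplication_events > 0L) {
    parents <- sample.int(nrow(genes), cfg$duplication_events)
    for (ev in seq_along(parents)) {
      p <- parents[ev]
      grp <- sprintf("pg%02d", ev)
      ancestral_prom <- genes$promoter[p]
      # parent keeps the block head, duplicate keeps the tail
      parent_prom <- ancestral_prom
      child_prom <- mutate_dna(ancestral_prom, 0.01)
      if (lost > 0L) {
        substr(parent_prom, bs + bl - lost, bs + bl - 1L) <-
          random_dna(lost)
        substr(child_prom, bs, bs + lost - 1L) <- random_dna(lost)
      }
      syn <- plant_synonymous(genes$cds[p])
      child_id <- paste0(genes$gene_id[p], "d")
      child_motif <- mutate_string(genes$dodecapeptide[p], within_rate, blosum)
      child_precursor <- paste0(
        SIGNAL_PEPTIDE,
        substr(
          genes$precursor[p], nchar(SIGNAL_PEPTIDE) + 1L,
          nchar(genes$precursor[p]) - 12L
        ),
        child_motif
      )
      child_cds <- derive_cds(syn$cds, genes$precursor[p], child_precursor)
      genes$promoter[p] <- parent_prom
      genes$paralog_group_truth[p] <- grp
      genes <- dplyr::bind_rows(genes, tibble(
        gene_id = child_id,
        species = genes$species[p],
        precursor = child_precursor,
        dodecapeptide = child_motif,
        cds = child_cds,
        promoter = child_prom,
        clade_truth = genes$clade_truth[p],
        paralog_group_truth = grp
      ))
      pairs[[ev]] <- tibble(
        gene_a = genes$gene_id[p], gene_b = child_id,
        ds_truth = syn$ds_truth,
        retained_a_start = bs, retained_a_end = bs + bl - 1L - lost,
        retained_b_start = bs + lost, retained_b_end = bs + bl - 1L
      )
    }
  }
  truth <- list(
    clade_partition = genes[, c("gene_id", "clade_truth")],
    paralog_pairs = if (length(pairs)) dplyr::bind_rows(pairs) else
      tibble(
        gene_a = character(), gene_b = character(), ds_truth = numeric(),
        retained_a_start = integer(), retained_a_end = integer(),
        retained_b_start = integer(), retained_b_end = integer()
      ),
    causal_genes = character(),
    generating_model = NULL
  )
  list(genes = genes, truth = truth)
}

#' Random sparse-coupling Potts model for benchmarking
#'
#' Draws per-site fields and places dense Gaussian coupling blocks on a random
#' subset of position pairs, with per-pair strength multipliers so the true
#' coupling-strength ranking has spread. Serves as the planted truth for
#' parameter-recovery checks.
#'
#' @param L motif length, `A` alphabet size.
#' @param A alphabet size.
#' @param n_coupled_pairs number of position pairs carrying couplings.
#' @param field_sd standard deviation of the fields.
#' @param coupling_sd baseline standard deviation of coupling entries; each
#'   coupled pair's entries are scaled by a Uniform(0.5, 1.5) multiplier.
#' @param seed integer seed.
#' @return a [potts_model()] with attribute `coupled_pairs` (matrix of pair
#'   indices).
#' @export
planted_potts_model <- function(L = 12, A = 20, n_coupled_pairs = 15,
                                field_sd = 0.3, coupling_sd = 1,
                                seed = 1) {
  withr::with_seed(seed, {
    h <- matrix(rnorm(L * A, sd = field_sd), L, A)
    J <- array(0, dim = c(L, L, A, A))
    all_pairs <- t(combn(L, 2))
    sel <- all_pairs[sample.int(nrow(all_pairs), n_coupled_pairs), ,
      drop = FALSE
    ]
    for (r in seq_len(nrow(sel))) {
      i <- sel[r, 1]
      j <- sel[r, 2]
      blk <- matrix(rnorm(A * A, sd = coupling_sd * runif(1, 0.5, 1.5)), A, A)
      J[i, j, , ] <- blk
      J[j, i, , ] <- t(blk)
    }
    m <- potts_model(h, J, alphabet = AA_ALPHABET[seq_len(A)])
    attr(m, "coupled_pairs") <- sel
    m
  })
}

#' Gibbs-sample sequences from a Potts model
#'
#' Runs `n` independent chains (one per output sequence) of single-site Gibbs
#' sampling for `burn_in` full sweeps over the `L` positions, then reports the
#' final state of each chain.
#'
#' @param model a [potts_model()].
#' @param n number of sequences; `n = 0` returns an empty character vector.
#' @param burn_in full Gibbs sweeps before reporting (default 100).
#' @param seed integer seed.
#' @return character vector of `n` sequences of length `model$L`.
#' @export
sample_potts_sequences <- function(model, n, burn_in = 100, seed = 1) {
  n <- check_count(n, "n", min = 0L)
  if (n == 0L) {
    return(character())
  }
  L <- model$L
  A <- model$A
  W <- potts_W(model)
  withr::with_seed(seed, {
    S <- matrix(sample.int(A, n * L, replace = TRUE), n, L)
    X <- one_hot(S, A)
    for (sweep_i in seq_len(burn_in)) {
      for (i in seq_len(L)) {
        blk <- ((i - 1) * A + 1):(i * A)
        # X's block i does not influence logits (zero diagonal blocks of W)
        logits <- sweep(X %*% W[, blk, drop = FALSE], 2, model$h[i, ], "+")
        new_s <- sample_categorical_rows(row_softmax(logits))
        S[, i] <- new_s
        X[, blk] <- 0
        X[cbind(seq_len(n), (i - 1L) * A + new_s)] <- 1
      }
    }
    apply(S, 1, function(r) chars_to_seq(model$alphabet[r]))
  })
}

#' Generate a three-population CRISPR pooled-sequencing experiment
#'
#' Every gene in `genes` is targeted with one knockout variant. Causal-gene
#' variants are fixed homozygous in the mutant-like pool, absent from the
#' WT-like pool, and segregate near 0.5 in the segregating pool; non-causal
#' variants segregate at a gene-specific frequency independent of phenotype
#' (identical across pools). Observed allele fractions are binomial draws at
#' the given read depth unless `noiseless = TRUE`. A few off-target rows
#' without gene assignment are appended.
#'
#' @param genes gene tibble (needs `gene_id`).
#' @param causal character vector of causal gene ids (subset of targets).
#' @param n_plants_per_pool plants pooled per population; the segregating
#'   pool's plant-level allele frequency is drawn binomially from 2N alleles.
#' @param depth sequencing depth per variant per pool.
#' @param seed integer seed.
#' @param noiseless skip binomial read sampling (report true pool fractions).
#' @param n_offtarget number of off-target rows.
#' @return list with `table` (tibble: chrom, pos, gene_id, consequence,
#'   af_seg, af_wt, af_mut, depth_seg, depth_wt, depth_mut) and `truth`
#'   (list with `causal_genes`).
#' @export
generate_three_pool_experiment <- function(genes, causal,
                                           n_plants_per_pool = 30,
                                           depth = 100, seed = 1,
                                           noiseless = FALSE,
                                           n_offtarget = 10) {
  if (!all(causal %in% genes$gene_id)) {
    abort("`causal` must be a subset of the targeted genes.")
  }
  depth <- check_count(depth, "depth")
  n_plants_per_pool <- check_count(n_plants_per_pool, "n_plants_per_pool")
  withr::with_seed(seed, {
    n <- nrow(genes)
    is_causal <- genes$gene_id %in% causal
    # true pool allele frequencies
    f_seg <- ifelse(is_causal,
      rbinom(n, 2L * n_plants_per_pool, 0.5) / (2 * n_plants_per_pool),
      NA_real_
    )
    f_gene <- runif(n, 0.2, 0.8) # phenotype-independent segregation
    freq_mut <- ifelse(is_causal, 1, f_gene)
    freq_wt <- ifelse(is_causal, 0, f_gene)
    freq_seg <- ifelse(is_causal, f_seg, f_gene)
    draw <- function(f) {
      if (noiseless) f else rbinom(length(f), depth, f) / depth
    }
    tab <- tibble(
      chrom = sprintf("chr%02d", 1L + (seq_len(n) - 1L) %% 12L),
      pos = sample.int(5e7, n),
      gene_id = genes$gene_id,
      consequence = sample(c("frameshift", "stop_gain", "motif_disrupting"),
        n,
        replace = TRUE
      ),
      af_seg = draw(freq_seg),
      af_wt = draw(freq_wt),
      af_mut = draw(freq_mut),
      depth_seg = depth, depth_wt = depth, depth_mut = depth
    )
    if (n_offtarget > 0L) {
      f_ot <- runif(n_offtarget, 0.2, 0.8)
      tab <- dplyr::bind_rows(tab, tibble(
        chrom = sprintf("chr%02d", sample.int(12L, n_offtarget,
          replace = TRUE
        )),
        pos = sample.int(5e7, n_offtarget),
        gene_id = NA_character_,
        consequence = "frameshift",
        af_seg = draw(f_ot), af_wt = draw(f_ot), af_mut = draw(f_ot),
        depth_seg = depth, depth_wt = depth, depth_mut = depth
      ))
    }
    list(table = tab, truth = list(causal_genes = causal))
  })
}

#' Generate a synthetic per-site conservation profile
#'
#' `n_conserved` positions are drawn uniformly above 0.6, the remainder below,
#' matching the thresholded aggregation in [conservation_score()].
#'
#' @param L number of positions.
#' @param n_conserved number of conserved positions (`<= L`).
#' @param seed integer seed.
#' @return numeric vector of length `L` in `[0, 1]`.
#' @export
generate_site_conservation <- function(L, n_conserved, seed = 1) {
  L <- check_count(L, "L")
  n_conserved <- check_count(n_conserved, "n_conserved", min = 0L)
  if (n_conserved > L) abort("`n_conserved` must not exceed L.")
  withr::with_seed(seed, {
    v <- runif(L, 0, 0.6)
    if (n_conserved > 0L) {
      idx <- sample.int(L, n_conserved)
      v[idx] <- runif(n_conserved, 0.6 + 1e-9, 1)
    }
    v
  })
}
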