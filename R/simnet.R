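# All-by-all peptide similarity network with E-value-like edge weights.
# Exact Smith-Waterman local alignment replaces heuristic BLASTp so the
# pipeline is deterministic; the Karlin-Altschul-style transform preserves the
# monotone score -> weight relationship a similarity network needs.

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score with affine gap penalties (a gap of length
#' `g` costs `gap_open + g * gap_extend`), computed exactly via
#' `Biostrings::pairwiseAlignment`.
#'
#' @param a,b amino-acid strings over the 20-letter alphabet.
#' @param matrix substitution matrix name or matrix (default BLOSUM62).
#' @param gap_open,gap_extend affine gap penalties (positive costs; defaults
#'   11 and 1, the BLASTp defaults).
#' @return single numeric alignment score (>= 0).
#' @export
align_pair <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                       gap_extend = 1) {
  if (nchar(a) == 0L || nchar(b) == 0L) abort("Sequences must be non-empty.")
  check_aa(a, "a")
  check_aa(b, "b")
  as.numeric(Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local",
    substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend,
    scoreOnly = TRUE
  ))
}

#' Convert an alignment score to a network edge weight
#'
#' Karlin-Altschul-style transform: the pseudo E-value is
#' `E = K * m * n * exp(-lambda * score)` and the weight is `-log10(E)`
#' clipped below at zero, i.e. strictly increasing in the score above the
#' `E = 1` boundary.
#'
#' @param score alignment score (>= 0); vectorized.
#' @param m query length in residues.
#' @param n database size in residues.
#' @param lambda,K Karlin-Altschul scale parameters (defaults 0.267 and
#'   0.041, the ungapped BLOSUM62/11/1 values).
#' @return non-negative weight(s).
#' @export
score_to_weight <- function(score, m, n, lambda = 0.267, K = 0.041) {
  if (m <= 0 || n <= 0) abort("`m` and `n` must be positive.")
  pmax(0, (lambda * score - log(K * m * n)) / log(10))
}

new_sim_graph <- function(nodes, edges, class = "sim_graph") {
  edges <- as_tibble(edges)
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  # canonical undirected storage: from < to, sorted
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- dplyr::arrange(dplyr::distinct(edges), .data$from, .data$to)
  structure(list(nodes = sort(nodes), edges = edges), class = class)
}

#' @export
print.sim_graph <- function(x, ...) {
  cat(sprintf(
    "<%s> %d nodes, %d edges\n", class(x)[1], length(x$nodes),
    nrow(x$edges)
  ))
  invisible(x)
}

#' @export
tidy.sim_graph <- function(x, ...) x$edges

# weighted adjacency matrix view (dense; node order = x$nodes)
graph_adjacency <- function(x) {
  n <- length(x$nodes)
  M <- matrix(0, n, n, dimnames = list(x$nodes, x$nodes))
  if (nrow(x$edges) > 0) {
    M[cbind(x$edges$from, x$edges$to)] <- x$edges$weight
    M[cbind(x$edges$to, x$edges$from)] <- x$edges$weight
  }
  M
}

#' Build the all-by-all peptide similarity graph
#'
#' Aligns every precursor pair with [align_pair()], converts scores to
#' `-log10` pseudo-E-value weights with [score_to_weight()] (database size =
#' total residues in the gene set), and keeps edges at or above `min_weight`
#' (default 0, i.e. E <= 1). Self-edges are excluded; storage is symmetric.
#'
#' @param genes gene tibble with `gene_id` and `precursor` columns.
#' @param min_weight minimum retained edge weight.
#' @param ... passed to [align_pair()].
#' @return a `sim_graph`: list with sorted `nodes` and an edge tibble
#'   `(from, to, weight)`.
#' @export
build_graph <- function(genes, min_weight = 0, ...) {
  if (nrow(genes) < 2L) abort("Need at least two genes.")
  if (anyDuplicated(genes$gene_id)) abort("Duplicate gene_id in input.")
  seqs <- genes$precursor
  ids <- genes$gene_id
  for (s in seqs) check_aa(s, "precursor")
  ndb <- sum(nchar(seqs))
  n <- length(seqs)
  edges <- vector("list", n - 1L)
  aa <- Biostrings::AAStringSet(seqs)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    sc <- Biostrings::pairwiseAlignment(
      pattern = aa[js], subject = aa[[i]], type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE
    )
    w <- score_to_weight(sc, m = nchar(seqs[i]), n = ndb)
    edges[[i]] <- tibble(from = ids[i], to = ids[js], weight = w)
  }
  e <- dplyr::bind_rows(edges)
  # weight 0 is the clipped E >= 1 floor: no evidence of similarity
  e <- e[e$weight >= min_weight & e$weight > 0, , drop = FALSE]
  new_sim_graph(ids, e)
}

#' Prune a similarity graph to each node's strongest connections
#'
#' An edge `(u, v)` is retained iff it ranks within the `k` heaviest edges of
#' `u` *or* of `v` (union semantics, biased toward keeping the graph
#' connected). Ties are broken by lexicographic partner id. Idempotent.
#'
#' @param graph a `sim_graph`.
#' @param k edges kept per node (default 500).
#' @return pruned `sim_graph`.
#' @export
prune_top_k <- function(graph, k = 500) {
  k <- check_count(k, "k")
  e <- graph$edges
  if (nrow(e) == 0L) {
    return(graph)
  }
  # rank each edge from both endpoints
  long <- dplyr::bind_rows(
    tibble(node = e$from, partner = e$to, weight = e$weight,
      id = seq_len(nrow(e))
    ),
    tibble(node = e$to, partner = e$from, weight = e$weight,
      id = seq_len(nrow(e))
    )
  )
  long <- long[order(long$node, -long$weight, long$partner), , drop = FALSE]
  long$rank <- stats::ave(seq_len(nrow(long)), long$node,
    FUN = seq_along
  )
  keep <- sort(unique(long$id[long$rank <= k]))
  new_sim_graph(graph$nodes, e[keep, , drop = FALSE], class = class(graph)[1])
}
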