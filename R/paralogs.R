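# Promoter-similarity network, seed labeling of shared-promoter groups, and
# semi-supervised label propagation over the embedding kNN graph.

#' Promoter similarity by canonical k-mer containment
#'
#' Containment Jaccard of canonical k-mer sets:
#' `|K(a) n K(b)| / min(|K(a)|, |K(b)|)`. Canonical k-mers (lexicographic
#' minimum of a k-mer and its reverse complement) make the comparison
#' strand-aware. Containment, unlike plain Jaccard, stays high when one
#' promoter retains only a fragment of a shared conserved block.
#'
#' @param a,b promoter DNA strings (length >= k).
#' @param k k-mer size (default 12).
#' @return similarity in `[0, 1]`.
#' @export
promoter_similarity <- function(a, b, k = 12) {
  ka <- canonical_kmers(a, k)
  kb <- canonical_kmers(b, k)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Build the all-pairs promoter similarity network
#'
#' @param genes gene tibble with `gene_id` and `promoter`. Genes with empty
#'   promoters are excluded with a warning.
#' @param min_sim minimum retained similarity (default 0.1).
#' @param k k-mer size (default 12).
#' @return a `promoter_network` (a `sim_graph` whose weights are similarities
#'   in `[0, 1]`).
#' @export
build_promoter_network <- function(genes, min_sim = 0.1, k = 12) {
  if (nrow(genes) < 2L) abort("Need at least two genes.")
  ok <- !is.na(genes$promoter) & nchar(genes$promoter) >= k
  if (any(!ok)) {
    warn(sprintf(
      "Excluding %d gene(s) without a usable promoter: %s",
      sum(!ok), paste(genes$gene_id[!ok], collapse = ", ")
    ))
    genes <- genes[ok, , drop = FALSE]
  }
  ids <- genes$gene_id
  ksets <- lapply(genes$promoter, canonical_kmers, k = k)
  sizes <- lengths(ksets)
  n <- length(ids)
  edges <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- length(intersect(ksets[[i]], ksets[[j]])) / min(sizes[i], sizes[j])
      if (s >= min_sim) {
        edges[[length(edges) + 1L]] <- tibble(
          from = ids[i], to = ids[j], weight = s
        )
      }
    }
  }
  e <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble(from = character(), to = character(), weight = numeric())
  g <- new_sim_graph(ids, e, class = "sim_graph")
  class(g) <- c("promoter_network", class(g))
  g
}

#' Semi-supervised label propagation over a kNN graph
#'
#' Synchronous iterative weighted-majority voting: each unlabeled node adopts
#' the label with the largest total incident edge weight among its neighbors'
#' current labels; seed nodes are clamped. A node whose vote is tied stays
#' unlabeled that round; remaining ties at termination break
#' lexicographically. Confidence is the winning label's weight share.
#'
#' @param knn a `sim_graph` (e.g. from [knn_graph()]).
#' @param seeds named vector gene_id -> group label (at least one).
#' @param max_iter iteration cap (default 100).
#' @return `label_state` tibble: gene_id, label, confidence, seeded.
#' @export
propagate_labels <- function(knn, seeds, max_iter = 100) {
  if (length(seeds) == 0L) abort("Need at least one seed.")
  nodes <- knn$nodes
  if (!all(names(seeds) %in% nodes)) {
    abort("All seed nodes must be present in the graph.")
  }
  W <- graph_adjacency(knn)
  labs <- setNames(rep(NA_character_, length(nodes)), nodes)
  labs[names(seeds)] <- as.character(seeds)
  seeded <- nodes %in% names(seeds)
  conf <- setNames(ifelse(seeded, 1, 0), nodes)
  vote_once <- function(labs, final = FALSE) {
    new_labs <- labs
    for (v in nodes[!seeded]) {
      nb <- which(W[v, ] > 0)
      nb_lab <- labs[nodes[nb]]
      ok <- !is.na(nb_lab)
      if (!any(ok)) next
      tot <- tapply(W[v, nb][ok], nb_lab[ok], sum)
      mx <- max(tot)
      winners <- sort(names(tot)[tot >= mx - 1e-12])
      if (length(winners) == 1L || final) {
        new_labs[[v]] <- winners[1]
        conf[[v]] <<- mx / sum(tot)
      } else {
        new_labs[[v]] <- NA_character_
      }
    }
    new_labs
  }
  for (it in seq_len(max_iter)) {
    new_labs <- vote_once(labs)
    if (identical(new_labs, labs)) break
    labs <- new_labs
  }
  labs <- vote_once(labs, final = TRUE)
  tibble(
    gene_id = nodes, label = unname(labs[nodes]),
    confidence = unname(conf[nodes]), seeded = seeded
  )
}

#' Assign paralog groups from promoter seeds and embedding neighborhoods
#'
#' Connected components of the promoter network at similarity
#' `>= sim_seed_threshold` become seed groups (singleton components seed their
#' own group); [propagate_labels()] then extends the seed labels over the
#' embedding kNN graph.
#'
#' @param genes gene tibble (for promoter exclusion warnings).
#' @param knn embedding kNN `sim_graph`.
#' @param promoter_network a `promoter_network`.
#' @param sim_seed_threshold similarity needed to share a seed group
#'   (default 0.5).
#' @return tibble gene_id, group, confidence, seeded.
#' @export
assign_paralog_groups <- function(genes, knn, promoter_network,
                                  sim_seed_threshold = 0.5) {
  e <- promoter_network$edges
  e <- e[e$weight >= sim_seed_threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(e[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = promoter_network$nodes)
  )
  comp <- igraph::components(g)$membership
  seeds <- setNames(paste0("G", comp), names(comp))
  st <- propagate_labels(knn, seeds)
  dplyr::rename(st, group = "label")
}
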