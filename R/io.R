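# Round-trip I/O for the pipeline's artifacts: FASTA, edge-list TSV, Newick,
# JSON model container, three-pool variant TSV.

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings; sequences are returned as a named character
#' vector (one record per gene id).
#'
#' @param path file path.
#' @param seqs named character vector.
#' @param type `"AA"` or `"DNA"`.
#' @return `read_fasta`: named character vector.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(sprintf("FASTA not found: %s", path))
  x <- if (type == "AA") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") {
    Biostrings::AAStringSet(seqs)
  } else {
    Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write a similarity graph as an edge-list TSV
#'
#' Columns `gene_a`, `gene_b`, `weight`. Isolated nodes are preserved through
#' a `# nodes:` header comment.
#'
#' @param graph a `sim_graph`.
#' @param path file path.
#' @return `read_graph_tsv`: a `sim_graph`.
#' @export
write_graph_tsv <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nodes: %s", paste(graph$nodes, collapse = ",")), con)
  writeLines("gene_a\tgene_b\tweight", con)
  if (nrow(graph$edges) > 0) {
    writeLines(sprintf(
      "%s\t%s\t%.10g", graph$edges$from, graph$edges$to,
      graph$edges$weight
    ), con)
  }
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(path) {
  lines <- readLines(path)
  nodes <- character()
  if (length(lines) > 0 && startsWith(lines[1], "# nodes:")) {
    nodes <- strsplit(sub("^# nodes: *", "", lines[1]), ",", fixed = TRUE)[[1]]
    lines <- lines[-1]
  }
  tab <- readr::read_tsv(I(paste(lines, collapse = "\n")),
    show_col_types = FALSE
  )
  if (!all(c("gene_a", "gene_b", "weight") %in% names(tab))) {
    abort(sprintf("Malformed edge list: %s", path))
  }
  nodes <- sort(unique(c(nodes, tab$gene_a, tab$gene_b)))
  new_sim_graph(nodes, tibble(
    from = tab$gene_a, to = tab$gene_b, weight = tab$weight
  ))
}

#' Serialize / load a Potts model as a JSON container
#'
#' Shape metadata plus full-precision fields and couplings; round-trips
#' bit-exactly (numbers are written with `digits = NA`).
#'
#' @param model a [potts_model()].
#' @param path file path.
#' @return `read_potts_json`: a [potts_model()].
#' @export
write_potts_json <- function(model, path) {
  obj <- list(
    L = model$L, A = model$A, alphabet = model$alphabet,
    lambda_h = model$lambda_h, lambda_J = model$lambda_J,
    theta = model$theta, neff = model$neff,
    h = as.vector(model$h), J = as.vector(model$J)
  )
  # digits = I(17) guarantees bit-exact double round-trips
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_potts_json
#' @export
read_potts_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- obj$L
  A <- obj$A
  potts_model(
    h = matrix(obj$h, L, A),
    J = array(obj$J, dim = c(L, L, A, A)),
    alphabet = obj$alphabet,
    lambda_h = obj$lambda_h %||% NA_real_,
    lambda_J = obj$lambda_J %||% NA_real_,
    theta = obj$theta %||% NA_real_,
    neff = obj$neff %||% NA_real_
  )
}

#' Read / write a three-pool variant table TSV
#'
#' VCF-like columns: chrom, pos, gene_id, consequence, af_seg, af_wt, af_mut,
#' depth_seg, depth_wt, depth_mut.
#'
#' @param table three-pool tibble.
#' @param path file path.
#' @return `read_three_pool_tsv`: tibble.
#' @export
write_three_pool_tsv <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname write_three_pool_tsv
#' @export
read_three_pool_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  for (col in intersect(c("chrom", "gene_id", "consequence"), names(tab))) {
    tab[[col]] <- as.character(tab[[col]])
  }
  need <- c(
    "chrom", "pos", "gene_id", "consequence",
    "af_seg", "af_wt", "af_mut"
  )
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    abort(sprintf(
      "Malformed three-pool table %s: missing %s", path,
      paste(missing, collapse = ", ")
    ))
  }
  tab
}

#' Write a Newick string to file
#'
#' @param newick single newick string (with trailing semicolon).
#' @param path file path.
#' @return `read_newick`: an `ape` `phylo` object.
#' @export
write_newick <- function(newick, path) {
  writeLines(newick, path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
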