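# Three-population CRISPR bulk-sequencing analysis: per-gene mutational index
# from pooled allele fractions, bottom-right candidate calling, promoter-
# network clustering significance, and expression-sample filtering.

DISRUPTIVE_DEFAULT <- c("frameshift", "stop_gain", "motif_disrupting")

#' Per-gene mutational index from a three-pool variant table
#'
#' For each on-target gene, over its disruptive-consequence variants:
#' `mi_mut` is the maximum mutant-pool allele fraction, `mi_wt` the WT-pool
#' fraction of that same variant, and `seg_support` whether the segregating
#' pool's fraction of that variant lies strictly between `tau_lo` and
#' `tau_hi`. Genes without disruptive variants are emitted with NA indices
#' (excluded from calling). Off-target rows (NA gene) are aggregated under
#' their `chrom:pos` identifier and flagged.
#'
#' @param table three-pool tibble (chrom, pos, gene_id, consequence, af_seg,
#'   af_wt, af_mut, depths).
#' @param tau_lo,tau_hi segregating-support interval (defaults 0.2, 0.8).
#' @param disruptive consequence classes counted as disruptive.
#' @return tibble: gene_id, mi_mut, mi_wt, seg_support, is_offtarget.
#' @export
mutational_index <- function(table, tau_lo = 0.2, tau_hi = 0.8,
                             disruptive = DISRUPTIVE_DEFAULT) {
  if (nrow(table) == 0L) abort("Empty variant table.")
  tab <- as_tibble(table)
  tab$is_offtarget <- is.na(tab$gene_id)
  tab$unit <- ifelse(tab$is_offtarget,
    paste0(tab$chrom, ":", tab$pos), tab$gene_id
  )
  tab |>
    dplyr::group_by(.data$unit, .data$is_offtarget) |>
    dplyr::summarise(.groups = "drop", {
      d <- dplyr::pick(dplyr::everything())
      dis <- d[d$consequence %in% disruptive, , drop = FALSE]
      if (nrow(dis) == 0L) {
        tibble(
          mi_mut = NA_real_, mi_wt = NA_real_, seg_support = NA
        )
      } else {
        top <- which.max(dis$af_mut)
        tibble(
          mi_mut = dis$af_mut[top],
          mi_wt = dis$af_wt[top],
          seg_support = dis$af_seg[top] > tau_lo & dis$af_seg[top] < tau_hi
        )
      }
    }) |>
    dplyr::rename(gene_id = "unit") |>
    dplyr::arrange(.data$is_offtarget, .data$gene_id)
}

#' Call candidate genes from mutational indices
#'
#' A gene is a candidate iff `mi_mut >= tau_hi`, `mi_wt <= tau_lo` and its
#' segregating support flag is set (the "bottom-right" corner of the
#' mutant-vs-WT index plane). Off-target units never become candidates.
#'
#' @param mis tibble from [mutational_index()].
#' @param tau_hi,tau_lo thresholds (defaults 0.8 and 0.2).
#' @return character vector of candidate gene ids (sorted).
#' @export
call_candidates <- function(mis, tau_hi = 0.8, tau_lo = 0.2) {
  ok <- !mis$is_offtarget & !is.na(mis$mi_mut) &
    mis$mi_mut >= tau_hi & mis$mi_wt <= tau_lo &
    !is.na(mis$seg_support) & mis$seg_support
  sort(mis$gene_id[ok])
}

#' Promoter-network clustering significance of a candidate set
#'
#' Statistic: mean pairwise promoter similarity among the candidates (absent
#' network edges count as 0). Null: the same statistic for `n_perm` uniform
#' random node sets of the same size; `p = (1 + #null >= observed) /
#' (n_perm + 1)`.
#'
#' @param candidates character vector of >= 2 gene ids, all network nodes.
#' @param network a `promoter_network`.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return `perm_test` object: `statistic`, `p_value`, `n_perm`, `null`.
#' @export
promoter_cluster_test <- function(candidates, network, n_perm = 999,
                                  seed = 1) {
  candidates <- unique(candidates)
  if (length(candidates) < 2L) abort("Need at least two candidates.")
  if (!all(candidates %in% network$nodes)) {
    abort("All candidates must be nodes of the promoter network.")
  }
  W <- graph_adjacency(network)
  mean_pairwise <- function(ids) {
    sub <- W[ids, ids, drop = FALSE]
    sum(sub[upper.tri(sub)]) / (length(ids) * (length(ids) - 1) / 2)
  }
  obs <- mean_pairwise(candidates)
  withr::with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(r) {
      mean_pairwise(sample(network$nodes, length(candidates)))
    }, numeric(1))
  })
  structure(
    list(
      statistic = obs, n_perm = n_perm, null = null,
      p_value = (1 + sum(null >= obs - 1e-12)) / (n_perm + 1)
    ),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> statistic = %.4f, p = %.4g (%d permutations)\n",
    x$statistic, x$p_value, x$n_perm
  ))
  invisible(x)
}

#' Filter expression samples by mapping rate and replicate agreement
#'
#' Drops samples with uniquely-mapped read rate at or below `min_mapping`
#' (default 0.5), then, within each replicate group of size >= 2, drops
#' samples whose median Spearman correlation of log-scaled TPM with the other
#' group members is at or below `min_cor` (default 0.75).
#'
#' @param tpm sample x gene numeric matrix or data frame (rownames =
#'   sample ids).
#' @param mapping_rates named vector sample -> uniquely-mapped fraction.
#' @param groups named vector sample -> replicate-group id.
#' @param min_mapping,min_cor retention thresholds.
#' @return character vector of retained sample ids.
#' @export
filter_expression_samples <- function(tpm, mapping_rates, groups,
                                      min_mapping = 0.5, min_cor = 0.75) {
  tpm <- as.matrix(tpm)
  if (nrow(tpm) == 0L || ncol(tpm) == 0L) abort("Empty expression table.")
  samples <- rownames(tpm)
  keep <- samples[mapping_rates[samples] > min_mapping]
  logt <- log2(tpm + 1)
  retained <- character()
  for (grp in unique(groups[keep])) {
    members <- keep[groups[keep] == grp]
    if (length(members) < 2L) {
      retained <- c(retained, members)
      next
    }
    cors <- suppressWarnings(
      cor(t(logt[members, , drop = FALSE]), method = "spearman")
    )
    med <- vapply(members, function(s) {
      stats::median(cors[s, setdiff(members, s)])
    }, numeric(1))
    retained <- c(retained, members[med > min_cor])
  }
  sort(retained)
}
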