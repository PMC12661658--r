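# Synonymous-distance estimation (Nei-Gojobori 1986 with Jukes-Cantor
# correction) and the paralog-versus-homolog mutational-burden comparison
# controlling for duplication age.

# Per-codon synonymous site fractions and the pathway machinery -----------------

stop_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc == "*"]
}

# S (synonymous) site count per codon: at each position, the fraction of the
# three possible point changes that are synonymous (stop outcomes count as
# nonsynonymous). Cached.
ng_site_env <- new.env(parent = emptyenv())

ng_site_table <- function() {
  if (!is.null(ng_site_env$tab)) {
    return(ng_site_env$tab)
  }
  gc <- genetic_code()
  codons <- names(gc)[gc != "*"]
  S <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    ch <- seq_to_chars(cd)
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(DNA_BASES, ch[p])) {
        alt <- ch
        alt[p] <- b
        alt_cd <- chars_to_seq(alt)
        if (gc[[alt_cd]] != "*" && gc[[alt_cd]] == gc[[cd]]) s <- s + 1 / 3
      }
    }
    S[cd] <- s
  }
  ng_site_env$tab <- list(S = S)
  ng_site_env$tab
}

# Pathway-averaged synonymous/nonsynonymous difference counts between two
# codons: average over all orderings of the differing positions, excluding
# pathways that pass through a stop codon (if every pathway does, all are
# kept, matching the usual convention of not leaving the pair uncounted).
codon_path_diffs <- function(c1, c2) {
  gc <- genetic_code()
  ch1 <- seq_to_chars(c1)
  ch2 <- seq_to_chars(c2)
  dpos <- which(ch1 != ch2)
  nd <- length(dpos)
  if (nd == 0L) {
    return(c(sd = 0, nd = 0))
  }
  perms <- if (nd == 1L) list(dpos) else {
    do.call(c, lapply(
      combinat_perms(nd),
      function(o) list(dpos[o])
    ))
  }
  count_path <- function(order_pos) {
    cur <- ch1
    sd <- 0
    nd_ <- 0
    for (p in order_pos) {
      nxt <- cur
      nxt[p] <- ch2[p]
      a <- gc[[chars_to_seq(cur)]]
      b <- gc[[chars_to_seq(nxt)]]
      if (b == "*" || a == "*") {
        return(NULL)
      }
      if (a == b) sd <- sd + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd_)
  }
  counted <- purrr::compact(lapply(perms, count_path))
  if (length(counted) == 0L) counted <- lapply(perms, function(o) {
    # all pathways hit a stop: count ignoring viability
    cur <- ch1
    sd <- 0
    nd_ <- 0
    for (p in o) {
      nxt <- cur
      nxt[p] <- ch2[p]
      same <- !is.na(genetic_code()[[chars_to_seq(cur)]]) &&
        genetic_code()[[chars_to_seq(cur)]] ==
          genetic_code()[[chars_to_seq(nxt)]]
      if (same) sd <- sd + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd_)
  })
  colMeans(do.call(rbind, counted))
}

combinat_perms <- function(n) {
  if (n == 1L) {
    return(list(1L))
  }
  out <- list()
  for (i in seq_len(n)) {
    for (rest in combinat_perms(n - 1L)) {
      tail_ <- seq_len(n)[-i][rest]
      out[[length(out) + 1L]] <- c(i, tail_)
    }
  }
  out
}

#' Synonymous distance between two coding sequences
#'
#' Nei-Gojobori (1986) counting: per-codon synonymous site fractions averaged
#' between the two sequences, pathway-averaged synonymous differences for
#' multi-hit codons, and the Jukes-Cantor correction
#' `dS = -3/4 * log(1 - 4/3 * p_s)`. When `p_s >= 3/4` the correction is
#' undefined and the pair is flagged saturated.
#'
#' @param cds_a,cds_b DNA coding strings: equal length, multiple of 3, no
#'   internal stop codons.
#' @return list with `ds` (NA when saturated), `ps`, `syn_sites`,
#'   `syn_diffs`, `saturated`.
#' @export
synonymous_distance <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) abort("CDS lengths differ.")
  n <- nchar(cds_a)
  if (n %% 3L != 0L) abort("CDS length must be divisible by 3.")
  ca <- substring(cds_a, seq(1L, n, 3L), seq(3L, n, 3L))
  cb <- substring(cds_b, seq(1L, n, 3L), seq(3L, n, 3L))
  gc <- genetic_code()
  if (any(gc[ca] == "*") || any(gc[cb] == "*")) {
    abort("Internal stop codon in CDS.")
  }
  S_tab <- ng_site_table()$S
  S <- (sum(S_tab[ca]) + sum(S_tab[cb])) / 2
  sd_tot <- 0
  for (i in seq_along(ca)) {
    if (ca[i] != cb[i]) {
      sd_tot <- sd_tot + codon_path_diffs(ca[i], cb[i])[["sd"]]
    }
  }
  ps <- if (S > 0) sd_tot / S else 0
  saturated <- ps >= 3 / 4
  ds <- if (saturated) NA_real_ else -3 / 4 * log(1 - 4 / 3 * ps)
  list(
    ds = ds, ps = ps, syn_sites = S, syn_diffs = sd_tot,
    saturated = saturated
  )
}

#' Column-majority consensus of equal-length motifs
#'
#' @param motifs character vector of equal-length sequences.
#' @return single consensus string (ties break alphabetically).
#' @export
consensus_motif <- function(motifs) {
  M <- seqs_to_matrix(motifs)
  chars_to_seq(apply(M, 2, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1]
  }))
}

#' Deleterious mutational burden of a sequence relative to a reference
#'
#' Sum over positions where the sequence differs from the reference of
#' `max(0, -dE)` for the reference-to-sequence substitution: only deleterious
#' contributions (negative energy differences under the model's sign
#' convention) accumulate.
#'
#' @param model a [potts_model()].
#' @param seq,reference amino-acid strings of length `model$L`.
#' @return non-negative burden.
#' @export
burden_score <- function(model, seq, reference) {
  if (nchar(seq) != nchar(reference)) abort("Sequence lengths differ.")
  s <- seq_to_chars(seq)
  r <- seq_to_chars(reference)
  tot <- 0
  for (i in which(s != r)) {
    de <- mutational_effect(model, reference, i, s[i])
    tot <- tot + max(0, -de)
  }
  tot
}

#' Build a burden-record table for paralog and homolog comparisons
#'
#' Paralog records compare each derived duplicate with its parent; homolog
#' records compare randomly paired non-paralog genes of the same clade.
#' Burden is computed against the clade column-majority consensus motif.
#'
#' @param genes gene tibble from [generate_family()].
#' @param model a fitted or planted [potts_model()] over the motifs.
#' @param truth truth list from [generate_family()] (for paralog pairs).
#' @param n_homolog_pairs homolog (non-paralog) comparisons to draw.
#' @param seed integer seed.
#' @return tibble: gene_id, reference_id, burden, ds, is_paralog_pair.
#' @export
build_burden_table <- function(genes, model, truth, n_homolog_pairs = 30,
                               seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    consensus <- genes |>
      dplyr::group_by(.data$clade_truth) |>
      dplyr::summarise(ref = consensus_motif(.data$dodecapeptide))
    ref_of <- setNames(consensus$ref, consensus$clade_truth)
    add_row <- function(a, b, is_par) {
      ga <- genes[genes$gene_id == a, ]
      gb <- genes[genes$gene_id == b, ]
      sdist <- synonymous_distance(ga$cds, gb$cds)
      tibble(
        gene_id = a, reference_id = b,
        burden = burden_score(
          model, ga$dodecapeptide, ref_of[[ga$clade_truth]]
        ),
        ds = sdist$ds, saturated = sdist$saturated,
        is_paralog_pair = is_par
      )
    }
    pp <- truth$paralog_pairs
    for (r in seq_len(nrow(pp))) {
      rows[[length(rows) + 1L]] <- add_row(pp$gene_b[r], pp$gene_a[r], TRUE)
    }
    nonpar <- genes$gene_id[is.na(genes$paralog_group_truth)]
    for (d in seq_len(n_homolog_pairs)) {
      repeat {
        pair <- sample(nonpar, 2L)
        same_clade <- genes$clade_truth[genes$gene_id == pair[1]] ==
          genes$clade_truth[genes$gene_id == pair[2]]
        if (same_clade) break
      }
      rows[[length(rows) + 1L]] <- add_row(pair[1], pair[2], FALSE)
    }
    dplyr::bind_rows(rows)
  })
}

#' Paralog mutational-burden test controlling for duplication age
#'
#' Least-squares fit of `burden ~ dS + is_paralog`; the paralog coefficient's
#' two-sided p-value comes from permuting the paralog flag within dS quartile
#' strata, honoring the `(1 + #extreme) / (n_perm + 1)` convention (never 0).
#' Strata containing a single class are dropped with a warning.
#'
#' @param records tibble with `burden`, `ds`, `is_paralog_pair` columns
#'   (saturated records, `ds` NA, are dropped).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return `burden_test` object: `estimate` (paralog coefficient), `p_value`,
#'   `n_perm`, `strata` (records per stratum), `n_used`.
#' @export
paralog_burden_test <- function(records, n_perm = 999, seed = 1) {
  rec <- records[!is.na(records$ds), , drop = FALSE]
  if (nrow(rec) == 0L) abort("No usable records (all dS missing).")
  if (!any(rec$is_paralog_pair) || all(rec$is_paralog_pair)) {
    abort("Need both paralog and non-paralog records.")
  }
  qs <- unique(quantile(rec$ds, probs = seq(0, 1, 0.25)))
  strata <- if (length(qs) > 2L) {
    cut(rec$ds, breaks = qs, include.lowest = TRUE)
  } else {
    factor(rep("all", nrow(rec)))
  }
  keep_lv <- levels(strata)[vapply(levels(strata), function(lv) {
    cls <- rec$is_paralog_pair[strata == lv]
    length(unique(cls)) == 2L
  }, logical(1))]
  dropped <- setdiff(levels(strata), keep_lv)
  if (length(dropped) > 0L) {
    warn(sprintf(
      "Dropping %d single-class dS stratum/strata.", length(dropped)
    ))
  }
  use <- strata %in% keep_lv
  if (!any(use)) abort("All dS strata are single-class; cannot permute.")
  rec <- rec[use, , drop = FALSE]
  strata <- droplevels(strata[use])
  X <- cbind(1, rec$ds, as.numeric(rec$is_paralog_pair))
  fit_coef <- function(flag) {
    Xp <- X
    Xp[, 3] <- flag
    qr.coef(qr(Xp), rec$burden)[3]
  }
  obs <- fit_coef(as.numeric(rec$is_paralog_pair))
  withr::with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(r) {
      flag <- rec$is_paralog_pair
      for (lv in levels(strata)) {
        idx <- which(strata == lv)
        flag[idx] <- flag[idx][sample.int(length(idx))]
      }
      fit_coef(as.numeric(flag))
    }, numeric(1))
  })
  if (!is.finite(obs) || obs == 0) {
    p <- 1
    obs <- if (is.finite(obs)) obs else 0
  } else {
    p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (n_perm + 1)
  }
  structure(
    list(
      estimate = unname(obs), p_value = p, n_perm = n_perm,
      strata = table(strata), n_used = nrow(rec), null = null
    ),
    class = "burden_test"
  )
}

#' @export
print.burden_test <- function(x, ...) {
  cat(sprintf(
    "<burden_test> paralog coefficient = %.4f, p = %.4g (n = %d, %d strata)\n",
    x$estimate, x$p_value, x$n_used, length(x$strata)
  ))
  invisible(x)
}
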