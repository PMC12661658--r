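# Validation regressions and conservation aggregation for mutational-effect
# landscapes.

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Regress mutational effects on BLOSUM substitution scores
#'
#' Ordinary least squares of the landscape's energy differences on the
#' BLOSUM62 score of each wild-type-to-mutant substitution, over all
#' non-wild-type cells. The residuals isolate the part of the predicted
#' mutational effect not explained by generic exchangeability, ready for
#' comparison against biochemical dissimilarity.
#'
#' @param landscape a [mutational_landscape()].
#' @param blosum substitution score matrix with residue dimnames; defaults to
#'   BLOSUM62 as shipped with Biostrings.
#' @return An object of class `blosum_fit`: list with `data` (tibble of
#'   position, wt_aa, mut_aa, delta_e, blosum, residual) and fit statistics
#'   `slope`, `intercept`, `r_squared`, `mse`, `spearman`.
#' @export
residualize_blosum <- function(landscape, blosum = NULL) {
  blosum <- blosum %||% blosum62_matrix()
  tb <- tidy(landscape)
  tb <- tb[tb$mut_aa != tb$wt_aa, , drop = FALSE]
  tb$blosum <- blosum[cbind(tb$wt_aa, tb$mut_aa)]
  if (length(unique(tb$blosum)) < 2L) {
    abort("Degenerate (constant) BLOSUM predictor; cannot regress.")
  }
  fit <- lm(delta_e ~ blosum, data = tb)
  tb$residual <- stats::resid(fit)
  structure(
    list(
      data = as_tibble(tb),
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = summary(fit)$r.squared,
      mse = mean(stats::resid(fit)^2),
      spearman = suppressWarnings(
        cor(tb$delta_e, tb$blosum, method = "spearman")
      )
    ),
    class = "blosum_fit"
  )
}

#' @export
print.blosum_fit <- function(x, ...) {
  cat(sprintf(
    "<blosum_fit> slope = %.3f, R^2 = %.3f, MSE = %.3f, rho = %.3f (n = %d)\n",
    x$slope, x$r_squared, x$mse, x$spearman, nrow(x$data)
  ))
  invisible(x)
}

#' Pairwise amino-acid biochemical dissimilarity
#'
#' A 20 x 20 dissimilarity built at run time from physicochemical property
#' scales in the AAindex collection shipped with seqinr (hydropathy, polarity,
#' volume, isoelectric point, bulkiness): properties are z-scored and pairwise
#' Euclidean distances rescaled to `[0, 1]`. This is a constructed index in the
#' spirit of Sneath's biochemical dissimilarity, not the literature table.
#'
#' @return symmetric 20 x 20 numeric matrix with residue dimnames, zero
#'   diagonal, values in `[0, 1]`.
#' @export
aa_dissimilarity <- function() {
  e <- new.env()
  utils::data("aaindex", package = "seqinr", envir = e)
  accs <- c(
    "KYTJ820101", # Kyte-Doolittle hydropathy
    "GRAR740102", # polarity
    "GRAR740103", # volume
    "ZIMJ680104", # isoelectric point
    "ZIMJ680102"  # bulkiness
  )
  props <- vapply(accs, function(a) {
    hit <- which(vapply(e$aaindex, function(x) x$H == a, logical(1)))
    v <- e$aaindex[[hit[1]]]$I
    # aaindex names entries by three-letter code
    names(v) <- seqinr::a(names(v))
    v[AA_ALPHABET]
  }, numeric(20))
  props <- scale(props)
  d <- as.matrix(dist(props))
  dimnames(d) <- list(AA_ALPHABET, AA_ALPHABET)
  d / max(d)
}

#' Correlate BLOSUM-residualized mutational effects with biochemical
#' dissimilarity
#'
#' Regresses the residual energy differences from [residualize_blosum()] on
#' the biochemical dissimilarity of each (wild-type, mutant) residue pair.
#' Under the sign convention that deleterious substitutions are negative, a
#' model that has internalized biochemistry shows a negative association.
#'
#' @param residuals a `blosum_fit` from [residualize_blosum()], or a data
#'   frame with columns `wt_aa`, `mut_aa`, `residual`.
#' @param dissimilarity 20 x 20 dissimilarity matrix with residue dimnames;
#'   defaults to [aa_dissimilarity()].
#' @return list with `r_squared`, `mse`, `spearman`, `slope` and the scored
#'   tibble in `data`.
#' @export
sneath_correlation <- function(residuals, dissimilarity = NULL) {
  dissimilarity <- dissimilarity %||% aa_dissimilarity()
  tb <- if (inherits(residuals, "blosum_fit")) residuals$data else
    as_tibble(residuals)
  if (!all(c("wt_aa", "mut_aa", "residual") %in% names(tb))) {
    abort("`residuals` needs columns wt_aa, mut_aa, residual.")
  }
  pairs <- cbind(tb$wt_aa, tb$mut_aa)
  if (!all(tb$wt_aa %in% rownames(dissimilarity)) ||
    !all(tb$mut_aa %in% colnames(dissimilarity))) {
    abort("Dissimilarity table is missing entries for some residue pairs.")
  }
  tb$dissimilarity <- dissimilarity[pairs]
  fit <- lm(residual ~ dissimilarity, data = tb)
  list(
    r_squared = summary(fit)$r.squared,
    mse = mean(stats::resid(fit)^2),
    spearman = suppressWarnings(
      cor(tb$residual, tb$dissimilarity, method = "spearman")
    ),
    slope = unname(coef(fit)[2]),
    data = as_tibble(tb)
  )
}

#' Aggregate site-level conservation into a single score
#'
#' The proportion of positions whose site-level value exceeds the threshold
#' (default 0.6).
#'
#' @param site_values numeric vector of per-position values in `[0, 1]`.
#' @param threshold cutoff above which a position counts as conserved.
#' @return proportion in `[0, 1]`.
#' @export
conservation_score <- function(site_values, threshold = 0.6) {
  if (length(site_values) == 0L) abort("Empty site-value vector.")
  mean(site_values > threshold)
}
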