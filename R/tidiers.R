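# broom-style tidiers and re-exported generics.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method
tidy.mutational_landscape <- function(x, ...) {
  L <- nrow(x$effects)
  A <- ncol(x$effects)
  wt <- seq_to_chars(x$wt)
  tibble(
    position = rep(seq_len(L), times = A),
    wt_aa = rep(wt, times = A),
    mut_aa = rep(x$alphabet, each = L),
    delta_e = as.vector(x$effects)
  )
}

#' @exportS3Method
tidy.potts_model <- function(x, ...) {
  tibble(
    position = rep(seq_len(x$L), times = x$A),
    residue = rep(x$alphabet, each = x$L),
    field = as.vector(x$h)
  )
}

#' @exportS3Method
glance.potts_model <- function(x, ...) {
  tibble(
    L = x$L, A = x$A, neff = x$neff,
    lambda_h = x$lambda_h, lambda_J = x$lambda_J, theta = x$theta,
    neg_logpl = attr(x, "neg_logpl") %||% NA_real_,
    convergence = attr(x, "convergence") %||% NA_integer_
  )
}

#' @exportS3Method
glance.blosum_fit <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    mse = x$mse, spearman = x$spearman, n = nrow(x$data)
  )
}

#' @exportS3Method
glance.sim_graph <- function(x, ...) {
  tibble(
    nodes = length(x$nodes), edges = nrow(x$edges),
    mean_weight = if (nrow(x$edges)) mean(x$edges$weight) else NA_real_
  )
}

#' @exportS3Method
tidy.gene_embedding <- function(x, ...) {
  v <- as_tibble(x$vectors, .name_repair = "minimal")
  names(v) <- paste0("v", seq_len(ncol(v)))
  dplyr::bind_cols(tibble(gene_id = rownames(x$vectors)), v)
}

#' @exportS3Method
tidy.hierarchy_tree <- function(x, ...) {
  purrr::imap_dfr(x$layers, function(lay, lev) {
    tibble(
      level = as.integer(lev), gene_id = names(lay),
      cluster = unname(lay)
    )
  })
}

#' @exportS3Method
glance.hierarchy_tree <- function(x, ...) {
  tibble(
    levels = length(x$layers),
    leaves = length(unique(x$layers[[length(x$layers)]])),
    genes = length(x$layers[[1]]),
    reassignments = x$n_reassignments %||% NA_integer_
  )
}

#' @exportS3Method
glance.burden_test <- function(x, ...) {
  tibble(
    estimate = x$estimate, p_value = x$p_value,
    n_perm = x$n_perm, n_strata = length(x$strata)
  )
}

#' @exportS3Method
glance.perm_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, n_perm = x$n_perm)
}
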