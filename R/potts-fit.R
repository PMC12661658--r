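# Regularized pseudolikelihood inference for Potts models on gapless motif
# alignments (plmDCA-style, full-batch quasi-Newton).

#' Sequence reweighting by identity clustering
#'
#' Each sequence is weighted by the reciprocal of the number of sequences
#' (itself included) with fractional identity at or above `theta`. The sum of
#' the weights is the effective sequence count `Neff`.
#'
#' @param msa character vector of equal-length, gapless amino-acid strings.
#' @param theta identity threshold in (0, 1]; default 0.8.
#' @return numeric vector of per-sequence weights with attribute `neff`.
#' @export
sequence_weights <- function(msa, theta = 0.8) {
  X <- aa_index_matrix(msa)
  n <- nrow(X)
  L <- ncol(X)
  # pairwise identity via one-hot cross-product
  oh <- one_hot(X, length(AA_ALPHABET))
  id <- tcrossprod(oh) / L
  w <- 1 / rowSums(id >= theta)
  attr(w, "neff") <- sum(w)
  w
}

# one-hot encode an n x L integer matrix into n x (L*A)
one_hot <- function(X, A) {
  n <- nrow(X)
  L <- ncol(X)
  oh <- matrix(0, n, L * A)
  cols <- sweep(X, 2, (seq_len(L) - 1L) * A, "+")
  oh[cbind(rep(seq_len(n), L), as.vector(cols))] <- 1
  oh
}

# Negative penalized weighted pseudolikelihood and its gradient.
# theta_vec layout: h (L*A) then upper-triangular coupling blocks (A*A each,
# column-major within block, blocks ordered (1,2),(1,3),...,(L-1,L)).
plm_objective <- function(theta_vec, X1h, Xidx, w, L, A, lambda_h, lambda_J,
                          grad = TRUE) {
  n <- nrow(X1h)
  nh <- L * A
  h <- matrix(theta_vec[seq_len(nh)], L, A, byrow = TRUE)
  W <- unpack_W(theta_vec, L, A)
  logits <- X1h %*% W # n x (L*A): coupling part
  obj <- 0
  D <- if (grad) matrix(0, n, L * A) else NULL
  for (i in seq_len(L)) {
    blk <- ((i - 1) * A + 1):(i * A)
    li <- sweep(logits[, blk, drop = FALSE], 2, h[i, ], "+")
    lse <- row_logsumexp(li)
    yi <- Xidx[, i]
    obj <- obj - sum(w * (li[cbind(seq_len(n), yi)] - lse))
    if (grad) {
      P <- exp(li - lse)
      P[cbind(seq_len(n), yi)] <- P[cbind(seq_len(n), yi)] - 1
      D[, blk] <- w * P
    }
  }
  # L2 penalties
  Jupper <- theta_vec[-seq_len(nh)]
  obj <- obj + lambda_h * sum(h^2) + lambda_J * sum(Jupper^2)
  if (!grad) {
    return(obj)
  }
  gh <- t(vapply(seq_len(L), function(i) {
    colSums(D[, ((i - 1) * A + 1):(i * A), drop = FALSE])
  }, numeric(A))) + 2 * lambda_h * h
  G <- crossprod(X1h, D) # d obj / d W_full
  G <- G + t(G) # symmetry: J_ij(a,b) appears at (i,a),(j,b) and (j,b),(i,a)
  gJ <- pack_upper(G, L, A) + 2 * lambda_J * Jupper
  list(value = obj, gradient = c(as.vector(t(gh)), gJ))
}

# build LA x LA symmetric W from packed parameter vector
unpack_W <- function(theta_vec, L, A) {
  W <- matrix(0, L * A, L * A)
  pos <- L * A
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      blk <- matrix(theta_vec[pos + seq_len(A * A)], A, A)
      W[((i - 1) * A + 1):(i * A), ((j - 1) * A + 1):(j * A)] <- blk
      W[((j - 1) * A + 1):(j * A), ((i - 1) * A + 1):(i * A)] <- t(blk)
      pos <- pos + A * A
    }
  }
  W
}

pack_upper <- function(G, L, A) {
  out <- numeric(L * (L - 1) / 2 * A * A)
  pos <- 0
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      out[pos + seq_len(A * A)] <-
        as.vector(G[((i - 1) * A + 1):(i * A), ((j - 1) * A + 1):(j * A)])
      pos <- pos + A * A
    }
  }
  out
}

#' Fit a Potts model by regularized pseudolikelihood
#'
#' Maximizes the weighted site-wise pseudolikelihood
#' `sum_s w_s sum_i log P(s_i | s_-i; h, J) - lambda_h ||h||^2 - lambda_J ||J||^2`
#' with L-BFGS-B from a zero start (the objective is convex, so the start does
#' not matter). Couplings are parameterized symmetrically, which is equivalent
#' to averaging the two conditional estimates of each block.
#'
#' @param msa character vector of equal-length gapless amino-acid strings.
#' @param weights optional per-sequence weights; when NULL they are computed
#'   with [sequence_weights()] at `theta`.
#' @param lambda_h,lambda_J L2 regularization strengths; defaults `0.01 * A`
#'   and `0.01 * A * (L - 1)`.
#' @param theta reweighting identity threshold (used when `weights` is NULL).
#' @param alphabet residue alphabet; defaults to the residues observed plus
#'   the standard 20 letters.
#' @param maxit maximum L-BFGS-B iterations.
#' @param reltol relative-objective convergence tolerance (default 1e-6).
#' @return a fitted [potts_model()] with elements `logpl` (final penalized
#'   negative objective) and `convergence` recorded as attributes.
#' @export
fit_potts <- function(msa, weights = NULL, lambda_h = NULL, lambda_J = NULL,
                      theta = 0.8, alphabet = AA_ALPHABET, maxit = 500,
                      reltol = 1e-6) {
  if (length(msa) == 0L) abort("Empty alignment.")
  Ls <- unique(nchar(msa))
  if (length(Ls) != 1L) abort("Ragged alignment: sequences differ in length.")
  L <- Ls
  if (L < 2L) abort("Motif length must be at least 2.")
  A <- length(alphabet)
  Xm <- seqs_to_matrix(msa)
  Xidx <- matrix(match(Xm, alphabet), nrow(Xm), ncol(Xm))
  if (anyNA(Xidx)) {
    abort(sprintf(
      "Invalid residue symbol(s): %s",
      paste(setdiff(unique(as.vector(Xm)), alphabet), collapse = ", ")
    ))
  }
  if (is.null(weights)) weights <- sequence_weights(msa, theta = theta)
  neff <- sum(weights)
  if (neff <= 0) abort("Neff is zero; nothing to fit.")
  lambda_h <- lambda_h %||% (0.01 * A)
  lambda_J <- lambda_J %||% (0.01 * A * (L - 1))
  X1h <- one_hot(Xidx, A)
  npar <- L * A + L * (L - 1) / 2 * A * A
  # L-BFGS-B asks for fn and gr at the same point back-to-back; cache the pair
  cache <- new.env(parent = emptyenv())
  evaluate <- function(p) {
    if (!is.null(cache$p) && identical(cache$p, p)) {
      return(cache$res)
    }
    res <- plm_objective(p, X1h, Xidx, weights, L, A, lambda_h, lambda_J)
    cache$p <- p
    cache$res <- res
    res
  }
  fn <- function(p) evaluate(p)$value
  gr <- function(p) evaluate(p)$gradient
  factr <- max(reltol / .Machine$double.eps, 10)
  opt <- optim(
    par = numeric(npar), fn = fn, gr = gr, method = "L-BFGS-B",
    control = list(maxit = maxit, factr = factr)
  )
  if (!all(is.finite(opt$par))) {
    abort("Non-finite parameters after optimization; check inputs.")
  }
  h <- matrix(opt$par[seq_len(L * A)], L, A, byrow = TRUE)
  J <- array(0, dim = c(L, L, A, A))
  pos <- L * A
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      blk <- matrix(opt$par[pos + seq_len(A * A)], A, A)
      J[i, j, , ] <- blk
      J[j, i, , ] <- t(blk)
      pos <- pos + A * A
    }
  }
  m <- potts_model(
    h = h, J = J, alphabet = alphabet, lambda_h = lambda_h,
    lambda_J = lambda_J, theta = theta, neff = neff
  )
  attr(m, "neg_logpl") <- opt$value
  attr(m, "convergence") <- opt$convergence
  m
}
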