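#' Construct a Potts model over fixed-length peptide motifs
#'
#' A Potts model places per-site fields `h` and pairwise couplings `J` over
#' sequences of fixed length `L` on an `A`-letter alphabet. The statistical
#' energy of a sequence is `E(s) = sum_i h[i, s_i] + sum_{i<j} J[i, j, s_i, s_j]`,
#' with the convention that *higher* energy means *more probable*: deleterious
#' substitutions therefore have negative energy differences.
#'
#' @param h numeric `L x A` field matrix.
#' @param J numeric `L x L x A x A` coupling array. Must satisfy
#'   `J[i, j, a, b] == J[j, i, b, a]` and have zero diagonal blocks
#'   (`J[i, i, , ] == 0`).
#' @param alphabet character vector of residue symbols (default the 20
#'   amino acids).
#' @param lambda_h,lambda_J L2 regularization strengths recorded on the model
#'   (informational for constructed models; set by [fit_potts()]).
#' @param theta sequence-reweighting identity threshold recorded on the model.
#' @param neff effective sequence count behind the model (NA for constructed
#'   models).
#'
#' @return An object of class `potts_model`.
#' @export
potts_model <- function(h, J, alphabet = AA_ALPHABET,
                        lambda_h = NA_real_, lambda_J = NA_real_,
                        theta = NA_real_, neff = NA_real_) {
  L <- nrow(h)
  A <- ncol(h)
  if (!identical(dim(J), c(L, L, A, A))) {
    abort("`J` must be an L x L x A x A array matching `h`.")
  }
  if (length(alphabet) != A) abort("`alphabet` length must equal ncol(h).")
  # enforce invariants exactly
  for (i in seq_len(L)) J[i, i, , ] <- 0
  Jp <- aperm(J, c(2, 1, 4, 3))
  if (max(abs(J - Jp)) > 1e-8) {
    abort("`J` must satisfy J[i,j,a,b] == J[j,i,b,a].")
  }
  J <- (J + Jp) / 2
  structure(
    list(
      L = L, A = A, h = h, J = J, alphabet = alphabet,
      lambda_h = lambda_h, lambda_J = lambda_J,
      theta = theta, neff = neff
    ),
    class = "potts_model"
  )
}

#' @export
print.potts_model <- function(x, ...) {
  cat(sprintf(
    "<potts_model> L = %d, A = %d, Neff = %s\n", x$L, x$A,
    ifelse(is.na(x$neff), "NA", format(round(x$neff, 1)))
  ))
  invisible(x)
}

# Flattened LA x LA symmetric coupling matrix view (zero diagonal blocks).
potts_W <- function(model) {
  L <- model$L
  A <- model$A
  W <- matrix(0, L * A, L * A)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      W[((i - 1) * A + 1):(i * A), ((j - 1) * A + 1):(j * A)] <-
        model$J[i, j, , ]
    }
  }
  W
}

#' Statistical energy of a sequence under a Potts model
#'
#' `E(s) = sum_i h[i, s_i] + sum_{i<j} J[i, j, s_i, s_j]`. Higher energy means
#' more probable under the model.
#'
#' @param model a [potts_model()].
#' @param s amino-acid string of length `model$L`.
#' @return a single numeric energy.
#' @export
potts_energy <- function(model, s) {
  if (nchar(s) != model$L) abort("Sequence length must equal model L.")
  idx <- match(seq_to_chars(s), model$alphabet)
  if (anyNA(idx)) check_aa(s)
  e <- sum(model$h[cbind(seq_len(model$L), idx)])
  for (i in seq_len(model$L - 1L)) {
    for (j in (i + 1L):model$L) {
      e <- e + model$J[i, j, idx[i], idx[j]]
    }
  }
  e
}

#' Energy difference of a point substitution
#'
#' Computes `E(mutant) - E(wild type)` incrementally: the field change at the
#' mutated site plus the coupling changes to every other position. Equal to the
#' full-energy difference, but O(L) instead of O(L^2). Substituting the
#' wild-type residue itself returns exactly 0. Negative values are deleterious.
#'
#' @param model a [potts_model()].
#' @param wt wild-type sequence (length `model$L`).
#' @param pos 1-based position of the substitution.
#' @param aa single-letter replacement residue.
#' @return numeric energy difference.
#' @export
mutational_effect <- function(model, wt, pos, aa) {
  L <- model$L
  if (nchar(wt) != L) abort("`wt` length must equal model L.")
  pos <- check_count(pos, "pos")
  if (pos > L) abort("`pos` exceeds motif length.")
  idx <- match(seq_to_chars(wt), model$alphabet)
  if (anyNA(idx)) check_aa(wt, "wt")
  a_new <- match(aa, model$alphabet)
  if (is.na(a_new)) abort(sprintf("Invalid residue symbol: %s", aa))
  a_old <- idx[pos]
  if (a_new == a_old) {
    return(0)
  }
  d <- model$h[pos, a_new] - model$h[pos, a_old]
  other <- setdiff(seq_len(L), pos)
  d + sum(model$J[pos, other, a_new, ][cbind(seq_along(other), idx[other])]) -
    sum(model$J[pos, other, a_old, ][cbind(seq_along(other), idx[other])])
}

#' Full single-substitution mutational landscape
#'
#' All `L x A` energy differences relative to a wild-type sequence. Wild-type
#' cells are exactly zero.
#'
#' @param model a [potts_model()].
#' @param wt wild-type sequence of length `model$L`.
#' @return An object of class `mutational_landscape`: list with `wt`,
#'   `effects` (`L x A` matrix, columns named by residue) and `alphabet`.
#'   Use [tidy()] for a long tibble.
#' @export
mutational_landscape <- function(model, wt) {
  L <- model$L
  A <- model$A
  eff <- matrix(0, L, A, dimnames = list(NULL, model$alphabet))
  for (i in seq_len(L)) {
    for (a in seq_len(A)) {
      eff[i, a] <- mutational_effect(model, wt, i, model$alphabet[a])
    }
  }
  structure(
    list(wt = wt, effects = eff, alphabet = model$alphabet),
    class = "mutational_landscape"
  )
}

#' @export
print.mutational_landscape <- function(x, ...) {
  cat(sprintf(
    "<mutational_landscape> wt = %s (%d x %d effects)\n",
    x$wt, nrow(x$effects), ncol(x$effects)
  ))
  invisible(x)
}

#' APC-corrected coupling-strength map
#'
#' Summarizes each coupling block in the zero-sum gauge by its Frobenius norm
#' and applies the average product correction (APC),
#' `F'_ij = F_ij - row_i(F) * col_j(F) / mean(F)`, the standard background
#' correction for site-entropy bias in contact maps. The diagonal is zero.
#'
#' @param model a fitted [potts_model()].
#' @param apc apply the average product correction (default TRUE).
#' @return `L x L` symmetric numeric matrix.
#' @export
coupling_map <- function(model, apc = TRUE) {
  L <- model$L
  FN <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      B <- model$J[i, j, , ]
      # zero-sum gauge per block
      B0 <- B - outer(rowMeans(B), rep(1, ncol(B))) -
        outer(rep(1, nrow(B)), colMeans(B)) + mean(B)
      FN[i, j] <- FN[j, i] <- sqrt(sum(B0^2))
    }
  }
  if (!apc) {
    return(FN)
  }
  out <- apc_correct(FN)
  diag(out) <- 0
  out
}

# Average product correction: F - rowmean %o% colmean / grandmean.
# Exactly annihilates rank-one matrices.
apc_correct <- function(FN) {
  gm <- mean(FN)
  if (gm == 0) {
    return(FN)
  }
  FN - outer(rowMeans(FN), colMeans(FN)) / gm
}
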