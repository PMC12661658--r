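tiny_model <- function(seed = 1, L = 4, A = 5) {
  planted_potts_model(
    L = L, A = A, n_coupled_pairs = 2, field_sd = 0.5,
    coupling_sd = 0.7, seed = seed
  )
}

test_that("sequence reweighting matches hand-enumerated neighbor counts", {
  msa <- c("AAAA", "AAAA", "AAAC", "CCCC", "CCCD")
  # identity matrix by hand at theta = 0.75: rows 1-3 mutually >= 0.75,
  # rows 4-5 mutually >= 0.75
  w <- sequence_weights(msa, theta = 0.75)
  expect_equal(as.numeric(w), c(1 / 3, 1 / 3, 1 / 3, 1 / 2, 1 / 2))
  expect_equal(attr(w, "neff"), 2)
  # n identical sequences: weights 1/n, Neff = 1
  w2 <- sequence_weights(rep("ACDE", 7), theta = 0.8)
  expect_equal(as.numeric(w2), rep(1 / 7, 7))
  expect_equal(attr(w2, "neff"), 1)
  # all pairs below theta: unit weights
  w3 <- sequence_weights(c("AAAA", "CCCC", "DDDD"), theta = 0.8)
  expect_equal(as.numeric(w3), c(1, 1, 1))
  expect_error(sequence_weights(c("AAA", "AAAA")), "length|Ragged")
})

test_that("analytic pseudolikelihood gradient matches central differences", {
  set.seed(4)
  L <- 3
  A <- 4
  msa <- replicate(25, paste(sample(aa20[1:A], L, TRUE), collapse = ""))
  Xidx <- matrix(match(
    unlist(strsplit(msa, "")), aa20[1:A]
  ), length(msa), L, byrow = TRUE)
  X1h <- pepfam:::one_hot(Xidx, A)
  w <- runif(length(msa), 0.5, 1.5)
  npar <- L * A + L * (L - 1) / 2 * A * A
  p <- rnorm(npar, sd = 0.3)
  f <- function(p) {
    pepfam:::plm_objective(p, X1h, Xidx, w, L, A, 0.1, 0.2, grad = FALSE)
  }
  analytic <- pepfam:::plm_objective(p, X1h, Xidx, w, L, A, 0.1, 0.2)$gradient
  numeric <- fd_gradient(f, p)
  expect_lt(
    max(abs(analytic - numeric)) / max(1, max(abs(numeric))), 1e-5
  )
})

test_that("energies equal naive double-loop summation", {
  m <- tiny_model(3)
  zero <- potts_model(
    matrix(0, m$L, m$A), array(0, dim = c(m$L, m$L, m$A, m$A)),
    alphabet = m$alphabet
  )
  withr::with_seed(8, {
    for (r in 1:20) {
      s <- paste(sample(m$alphabet, m$L, TRUE), collapse = "")
      idx <- match(strsplit(s, "")[[1]], m$alphabet)
      naive <- sum(m$h[cbind(1:m$L, idx)])
      for (i in 1:(m$L - 1)) {
        for (j in (i + 1):m$L) naive <- naive + m$J[i, j, idx[i], idx[j]]
      }
      expect_equal(potts_energy(m, s), naive)
      expect_equal(potts_energy(zero, s), 0)
    }
  })
  h1 <- matrix(0, 3, 5)
  h1[1, 1] <- 2.5 # single field on residue A at position 1
  m1 <- potts_model(h1, array(0, dim = c(3, 3, 5, 5)), alphabet = aa20[1:5])
  expect_equal(potts_energy(m1, "ACC"), 2.5)
  expect_equal(potts_energy(m1, "CCC"), 0)
  expect_error(potts_energy(m, "ZZZZ"), "Invalid")
})

test_that("incremental mutational effects equal full-energy differences", {
  m <- tiny_model(5)
  wt <- sample_potts_sequences(m, 1, burn_in = 5, seed = 2)
  expect_equal(mutational_effect(m, wt, 2, substr(wt, 2, 2)), 0)
  withr::with_seed(11, {
    for (r in 1:100) {
      pos <- sample(m$L, 1)
      aa <- sample(m$alphabet, 1)
      mut <- wt
      substr(mut, pos, pos) <- aa
      expect_equal(
        mutational_effect(m, wt, pos, aa),
        potts_energy(m, mut) - potts_energy(m, wt)
      )
    }
  })
  # with zero couplings the effect is the analytic field difference
  mJ0 <- potts_model(m$h, array(0, dim = c(m$L, m$L, m$A, m$A)),
    alphabet = m$alphabet
  )
  idx <- match(strsplit(wt, "")[[1]], m$alphabet)
  expect_equal(
    mutational_effect(mJ0, wt, 3, m$alphabet[2]),
    m$h[3, 2] - m$h[3, idx[3]]
  )
})

test_that("landscapes are elementwise-consistent with zero wild-type column", {
  m <- tiny_model(6)
  wt <- sample_potts_sequences(m, 1, burn_in = 5, seed = 3)
  land <- mutational_landscape(m, wt)
  wt_ch <- strsplit(wt, "")[[1]]
  for (i in seq_len(m$L)) {
    expect_identical(unname(land$effects[i, wt_ch[i]]), 0)
    for (a in seq_len(m$A)) {
      expect_equal(
        unname(land$effects[i, a]),
        mutational_effect(m, wt, i, m$alphabet[a])
      )
    }
  }
  zero <- potts_model(
    matrix(0, m$L, m$A), array(0, dim = c(m$L, m$L, m$A, m$A)),
    alphabet = m$alphabet
  )
  expect_true(all(mutational_landscape(zero, wt)$effects == 0))
})

test_that("coupling maps are symmetric, zero for null models, APC-exact on rank one", {
  m <- tiny_model(7)
  cm <- coupling_map(m)
  expect_equal(cm, t(cm))
  expect_true(all(diag(cm) == 0))
  zero <- potts_model(
    matrix(0, 4, 5), array(0, dim = c(4, 4, 5, 5)),
    alphabet = aa20[1:5]
  )
  expect_true(all(coupling_map(zero) == 0))
  u <- c(1, 2.5, 0.3, 4)
  expect_lt(max(abs(pepfam:::apc_correct(outer(u, u)))), 1e-12)
})

test_that("gauge shifts that cancel leave all energies and effects unchanged", {
  m <- tiny_model(9)
  wt <- strrep("A", 4)
  land0 <- mutational_landscape(m, wt)
  # add c to row i of h and subtract c/(L-1) from every entry of each block
  # J[i, j, , ]: the two moves cancel in every sequence energy
  shift <- 0.7
  i <- 2
  h2 <- m$h
  h2[i, ] <- h2[i, ] + shift
  J2 <- m$J
  for (j in seq_len(m$L)[-i]) {
    J2[i, j, , ] <- J2[i, j, , ] - shift / (m$L - 1)
    J2[j, i, , ] <- J2[j, i, , ] - shift / (m$L - 1)
  }
  m2 <- potts_model(h2, J2, alphabet = m$alphabet)
  withr::with_seed(2, {
    for (r in 1:10) {
      s <- paste(sample(m$alphabet, m$L, TRUE), collapse = "")
      expect_equal(potts_energy(m2, s), potts_energy(m, s),
        tolerance = 1e-12
      )
    }
  })
  land2 <- mutational_landscape(m2, wt)
  expect_equal(land2$effects, land0$effects, tolerance = 1e-12)
})

test_that("independent-site data yields field-only fits with null-level couplings", {
  set.seed(21)
  A <- 6
  L <- 4
  probs <- t(apply(matrix(rexp(L * A), L, A), 1, function(x) x / sum(x)))
  msa <- vapply(seq_len(600), function(s) {
    paste(vapply(seq_len(L), function(i) {
      sample(aa20[1:A], 1, prob = probs[i, ])
    }, character(1)), collapse = "")
  }, character(1))
  fit <- fit_potts(msa, weights = rep(1, length(msa)), alphabet = aa20[1:A])
  # fitted per-site conditionals track empirical frequencies
  emp <- t(vapply(seq_len(L), function(i) {
    as.numeric(table(factor(substr(msa, i, i), levels = aa20[1:A]))) /
      length(msa)
  }, numeric(A)))
  mod <- t(apply(fit$h, 1, function(hr) exp(hr) / sum(exp(hr))))
  expect_lt(max(abs(emp - mod)), 0.1)
  # coupling norms indistinguishable from a column-permuted null fit
  msa_perm <- vapply(seq_len(length(msa)), function(s) msa[s], character(1))
  M <- do.call(rbind, strsplit(msa, ""))
  for (i in seq_len(L)) M[, i] <- M[sample(nrow(M)), i]
  null_fit <- fit_potts(apply(M, 1, paste, collapse = ""),
    weights = rep(1, length(msa)), alphabet = aa20[1:A]
  )
  fn <- function(f) sqrt(sum(f$J^2))
  expect_lt(fn(fit), fn(null_fit) * 1.5 + 1e-9)
})

test_that("duplicating every sequence with reweighting leaves the fit unchanged", {
  m <- tiny_model(10, L = 3, A = 4)
  msa <- sample_potts_sequences(m, 150, burn_in = 10, seed = 4)
  f1 <- fit_potts(msa, theta = 0.9, alphabet = m$alphabet)
  f2 <- fit_potts(c(msa, msa), theta = 0.9, alphabet = m$alphabet)
  expect_equal(f1$h, f2$h, tolerance = 1e-4)
  expect_equal(f1$J, f2$J, tolerance = 1e-4)
})

test_that("BLOSUM residualization recovers planted linear structure", {
  m <- tiny_model(12, L = 5, A = 20)
  wt <- strrep("A", 5)
  land <- mutational_landscape(m, wt)
  # plant exact linearity in the BLOSUM score
  B <- blosum62
  for (i in seq_len(5)) {
    for (a in seq_len(20)) {
      land$effects[i, a] <- 0.5 * B["A", aa20[a]] - 1
    }
    land$effects[i, "A"] <- 0
  }
  # wild-type cells (score of A->A) sit off the line; drop via the non-wt rule
  fit <- residualize_blosum(land)
  expect_gt(fit$r_squared, 0.999)
  expect_lt(max(abs(fit$data$residual)), 1e-8)
  expect_equal(fit$slope, 0.5, tolerance = 1e-8)
  # fit statistics equal the closed-form normal equations
  tb <- tidy(land)
  tb <- tb[tb$mut_aa != tb$wt_aa, ]
  x <- B[cbind(tb$wt_aa, tb$mut_aa)]
  y <- tb$delta_e
  beta <- cov(x, y) / var(x)
  expect_equal(fit$slope, beta, tolerance = 1e-10)
  expect_equal(fit$intercept, mean(y) - beta * mean(x), tolerance = 1e-10)
})

test_that("dissimilarity correlation is exact on planted monotone residuals", {
  d <- aa_dissimilarity()
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  withr::with_seed(3, {
    tb <- tibble::tibble(
      wt_aa = sample(aa20, 40, TRUE),
      mut_aa = sample(aa20, 40, TRUE)
    )
  })
  tb <- tb[tb$wt_aa != tb$mut_aa, ]
  tb$residual <- -2 * d[cbind(tb$wt_aa, tb$mut_aa)]
  res <- sneath_correlation(tb)
  expect_equal(res$spearman, -1)
  expect_gt(res$r_squared, 0.999)
  # shuffled residuals: negligible association
  tb2 <- tb
  tb2$residual <- withr::with_seed(5, sample(tb$residual))
  expect_lt(abs(sneath_correlation(tb2)$spearman), 0.45)
  expect_error(
    sneath_correlation(tb, dissimilarity = d[1:5, 1:5]),
    "missing"
  )
})

test_that("conservation score is the thresholded proportion with 0.6 default", {
  expect_equal(conservation_score(c(0.7, 0.5, 0.9)), 2 / 3)
  expect_equal(conservation_score(c(0.61, 0.99)), 1)
  expect_equal(formals(conservation_score)$threshold, 0.6)
  expect_error(conservation_score(numeric()), "Empty")
})

test_that("model containers round-trip bit-exactly", {
  m <- tiny_model(15)
  path <- withr::local_tempfile(fileext = ".json")
  write_potts_json(m, path)
  m2 <- read_potts_json(path)
  expect_identical(m$h, m2$h)
  expect_identical(m$J, m2$J)
  expect_identical(m$alphabet, m2$alphabet)
})
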