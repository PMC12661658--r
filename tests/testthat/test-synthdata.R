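test_that("family generation is seed-deterministic and zero-rate collapses clades", {
  cfg <- family_sim_config(
    n_clades = 3, genes_per_clade = 5,
    duplication_events = 2, seed = 11
  )
  f1 <- generate_family(cfg)
  f2 <- generate_family(cfg)
  expect_identical(f1, f2)

  cfg0 <- family_sim_config(
    n_clades = 3, genes_per_clade = 5, motif_divergence = 0,
    duplication_events = 0, seed = 4
  )
  f0 <- generate_family(cfg0)
  per_clade <- split(f0$genes$dodecapeptide, f0$genes$clade_truth)
  for (motifs in per_clade) expect_length(unique(motifs), 1L)
})

test_that("gene records satisfy the precursor/motif/CDS invariants", {
  fam <- generate_family(family_sim_config(
    n_clades = 2, genes_per_clade = 4, duplication_events = 2, seed = 9
  ))
  g <- fam$genes
  expect_true(all(nchar(g$dodecapeptide) == 12L))
  expect_true(all(nchar(g$cds) %% 3L == 0L))
  for (i in seq_len(nrow(g))) {
    aa <- pepfam:::translate_cds(g$cds[i])
    expect_false(grepl("*", aa, fixed = TRUE))
    expect_identical(aa, g$precursor[i])
    expect_identical(substr(aa, nchar(aa) - 11L, nchar(aa)), g$dodecapeptide[i])
  }
  expect_true(all(g$gene_id %in% fam$truth$clade_partition$gene_id))
})

test_that("half-block erosion yields disjoint retained halves tiling the block", {
  cfg <- family_sim_config(
    n_clades = 2, genes_per_clade = 4, erosion_asymmetry = 0.5,
    cns_block = c(start = 101, length = 200), duplication_events = 3,
    seed = 21
  )
  fam <- generate_family(cfg)
  pp <- fam$truth$paralog_pairs
  expect_equal(nrow(pp), 3L)
  for (r in seq_len(nrow(pp))) {
    ra <- seq(pp$retained_a_start[r], pp$retained_a_end[r])
    rb <- seq(pp$retained_b_start[r], pp$retained_b_end[r])
    expect_length(intersect(ra, rb), 0L)
    expect_setequal(union(ra, rb), seq(101, 300))
  }
  # zero erosion: the pair shares the full ancestral block
  fam0 <- generate_family(family_sim_config(
    n_clades = 2, genes_per_clade = 4, erosion_asymmetry = 0,
    duplication_events = 1, seed = 3
  ))
  pp0 <- fam0$truth$paralog_pairs
  expect_equal(pp0$retained_a_start, pp0$retained_b_start)
  expect_equal(pp0$retained_a_end, pp0$retained_b_end)
})

test_that("degenerate configurations are rejected", {
  expect_error(family_sim_config(n_clades = 0), "n_clades")
  expect_error(
    family_sim_config(cns_block = c(start = 900, length = 200)),
    "within the promoter"
  )
  expect_error(family_sim_config(motif_divergence = 1.5), "motif_divergence")
})

test_that("zero-parameter Potts sampling is uniform per position", {
  L <- 3
  A <- 6
  m0 <- potts_model(
    h = matrix(0, L, A), J = array(0, dim = c(L, L, A, A)),
    alphabet = aa20[seq_len(A)]
  )
  s <- sample_potts_sequences(m0, 10000, burn_in = 5, seed = 2)
  M <- matrix(unlist(strsplit(s, "")), length(s), L, byrow = TRUE)
  p0 <- 1 / A
  se <- sqrt(p0 * (1 - p0) / length(s))
  for (pos in seq_len(L)) {
    freqs <- table(factor(M[, pos], levels = aa20[seq_len(A)])) / length(s)
    expect_true(all(abs(freqs - p0) < 3 * se + 1e-9))
  }
})

test_that("field-only sampling matches the exact single-site Boltzmann law", {
  L <- 2
  A <- 4
  h <- matrix(0, L, A)
  h[1, 2] <- 1.5
  m <- potts_model(h, array(0, dim = c(L, L, A, A)), alphabet = aa20[1:A])
  s <- sample_potts_sequences(m, 8000, burn_in = 10, seed = 7)
  first <- substr(s, 1, 1)
  p_exact <- exp(h[1, ]) / sum(exp(h[1, ]))
  freqs <- as.numeric(table(factor(first, levels = aa20[1:A]))) / length(s)
  expect_true(which.max(freqs) == 2L)
  se <- sqrt(p_exact * (1 - p_exact) / length(s))
  expect_true(all(abs(freqs - p_exact) < 4 * se + 1e-9))
})

test_that("a coupled L=2, A=2 model reproduces the exact 4-state Boltzmann", {
  A <- 2
  h <- matrix(c(0.2, -0.1, 0, 0.3), 2, A)
  J <- array(0, dim = c(2, 2, A, A))
  blk <- matrix(c(0.8, -0.5, -0.2, 0.4), A, A)
  J[1, 2, , ] <- blk
  J[2, 1, , ] <- t(blk)
  m <- potts_model(h, J, alphabet = c("A", "C"))
  states <- expand.grid(a = 1:2, b = 1:2)
  en <- apply(states, 1, function(st) {
    h[1, st[1]] + h[2, st[2]] + blk[st[1], st[2]]
  })
  p_exact <- exp(en) / sum(exp(en))
  s <- sample_potts_sequences(m, 20000, burn_in = 30, seed = 5)
  lab <- paste0(c("A", "C")[match(substr(s, 1, 1), c("A", "C"))],
    c("A", "C")[match(substr(s, 2, 2), c("A", "C"))]
  )
  key <- paste0(c("A", "C")[states$a], c("A", "C")[states$b])
  freqs <- as.numeric(table(factor(lab, levels = key))) / length(s)
  se <- sqrt(p_exact * (1 - p_exact) / length(s))
  expect_true(all(abs(freqs - p_exact) < 4 * se + 1e-9))
  expect_identical(sample_potts_sequences(m, 0, seed = 1), character())
})

test_that("noiseless three-pool experiments have the definitional geometry", {
  fam <- generate_family(family_sim_config(
    n_clades = 2, genes_per_clade = 5, duplication_events = 0, seed = 2
  ))
  causal <- fam$genes$gene_id[c(1, 5)]
  exp1 <- generate_three_pool_experiment(fam$genes, causal,
    seed = 3,
    noiseless = TRUE
  )
  tab <- exp1$table[!is.na(exp1$table$gene_id), ]
  ctab <- tab[tab$gene_id %in% causal, ]
  expect_true(all(ctab$af_mut == 1))
  expect_true(all(ctab$af_wt == 0))
  expect_true(all(ctab$af_seg > 0 & ctab$af_seg < 1))
  # no causal genes -> nobody shows the (high, low, intermediate) pattern
  exp0 <- generate_three_pool_experiment(fam$genes, character(),
    seed = 4,
    noiseless = TRUE
  )
  t0 <- exp0$table[!is.na(exp0$table$gene_id), ]
  pattern <- t0$af_mut >= 0.8 & t0$af_wt <= 0.2 &
    t0$af_seg > 0.2 & t0$af_seg < 0.8
  expect_false(any(pattern))
  expect_error(
    generate_three_pool_experiment(fam$genes, causal, depth = 0, seed = 1),
    "depth"
  )
  expect_error(
    generate_three_pool_experiment(fam$genes, "not_a_gene", seed = 1),
    "subset"
  )
})

test_that("binomial read sampling respects exact binomial quantiles", {
  # planted 0.5-frequency variant at depth 100: the observed fraction must
  # fall inside the central 99% binomial interval in >= 99% of seeds
  lo <- qbinom(0.005, 100, 0.5) / 100
  hi <- qbinom(0.995, 100, 0.5) / 100
  genes <- tibble::tibble(gene_id = "g1")
  hits <- vapply(1:300, function(s) {
    tab <- generate_three_pool_experiment(genes, "g1",
      depth = 100,
      n_plants_per_pool = 1e6, seed = s, n_offtarget = 0
    )$table
    tab$af_seg[1] >= lo && tab$af_seg[1] <= hi
  }, logical(1))
  expect_gte(mean(hits), 0.97)
})

test_that("site-conservation profiles match the thresholded proportion", {
  expect_equal(conservation_score(generate_site_conservation(10, 4, 1)), 0.4)
  expect_equal(conservation_score(generate_site_conservation(7, 7, 2)), 1.0)
  expect_equal(conservation_score(generate_site_conservation(7, 0, 3)), 0.0)
  expect_error(generate_site_conservation(5, 6), "exceed")
})
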