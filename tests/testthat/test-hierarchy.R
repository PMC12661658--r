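test_that("CPM communities equal exhaustive optima on small graphs", {
  # two disconnected triangles: any gamma below within-clique density
  tri2 <- make_graph(tibble::tibble(
    from = c("a1", "a1", "a2", "b1", "b1", "b2"),
    to = c("a2", "a3", "a3", "b2", "b3", "b3"),
    weight = 1
  ))
  parts <- multires_communities(tri2, resolutions = 0.5, seed = 1)
  memb <- stats::setNames(parts[[1]]$community, parts[[1]]$gene_id)
  expect_equal(ari(memb, rep(1:2, each = 3)), 1)
  oracle <- cpm_oracle(tri2, 0.5)
  expect_equal(cpm_quality(tri2, memb, 0.5), oracle$quality)
  # random graphs, n <= 8: Leiden quality equals the exhaustive optimum
  for (seed in 1:4) {
    g <- random_small_graph(6 + seed %% 3, seed)
    for (gamma in c(0.3, 1)) {
      parts <- multires_communities(g, resolutions = gamma, seed = seed)
      memb <- stats::setNames(parts[[1]]$community, parts[[1]]$gene_id)
      expect_equal(
        cpm_quality(g, memb, gamma), cpm_oracle(g, gamma)$quality,
        tolerance = 1e-9, info = paste("seed", seed, "gamma", gamma)
      )
    }
  }
})

test_that("CPM resolution extremes give components and singletons", {
  g <- random_small_graph(7, 3, p = 0.6)
  low <- multires_communities(g, resolutions = 1e-6, seed = 1)[[1]]
  n_comp <- igraph::components(igraph::graph_from_data_frame(
    g$edges[, 1:2],
    directed = FALSE, vertices = data.frame(name = g$nodes)
  ))$no
  expect_equal(length(unique(low$community)), n_comp)
  high <- multires_communities(g, resolutions = 1e6, seed = 1)[[1]]
  expect_equal(length(unique(high$community)), length(g$nodes))
})

test_that("reconciliation reproduces nested inputs exactly", {
  genes <- paste0("g", 1:8)
  P1 <- stats::setNames(rep(c("A", "B"), each = 4), genes)
  P2 <- stats::setNames(rep(c("x", "y", "z", "w"), each = 2), genes)
  tr <- reconcile_tree(list(P1, P2))
  expect_equal(tr$n_reassignments, 0L)
  expect_true(pepfam:::tree_is_nested(tr))
  expect_equal(
    ari(tr$layers[[1]], P1), 1
  )
  expect_equal(ari(tr$layers[[2]], P2), 1)
  # single partition: two-level semantics (root + communities)
  tr1 <- reconcile_tree(list(P1))
  expect_length(tr1$layers, 1L)
  expect_equal(ari(tr1$layers[[1]], P1), 1)
  expect_error(reconcile_tree(list()), "Empty")
})

test_that("one flipped gene costs exactly one reassignment (brute-force minimum)", {
  genes <- paste0("g", 1:6)
  P1 <- stats::setNames(rep(c("A", "B"), each = 3), genes)
  P2 <- stats::setNames(c("x", "x", "x", "y", "y", "x"), genes) # g6 flipped
  tr <- reconcile_tree(list(P1, P2))
  expect_true(pepfam:::tree_is_nested(tr))
  expect_equal(tr$n_reassignments, reconcile_oracle_2layer(P1, P2))
  expect_equal(tr$n_reassignments, 1L)
})

test_that("reconciliation matches the brute-force minimum on random inputs", {
  for (seed in 1:6) {
    withr::with_seed(seed, {
      n <- sample(5:7, 1)
      genes <- paste0("g", seq_len(n))
      P1 <- stats::setNames(sample(c("A", "B"), n, replace = TRUE), genes)
      P2 <- stats::setNames(sample(c("x", "y", "z"), n, replace = TRUE), genes)
    })
    tr <- reconcile_tree(list(P1, P2))
    expect_true(pepfam:::tree_is_nested(tr))
    expect_equal(tr$n_reassignments, reconcile_oracle_2layer(P1, P2),
      info = paste("seed", seed)
    )
  }
})

test_that("sister pruning merges identical-motif leaves and keeps distinct ones", {
  genes <- paste0("g", 1:12)
  P1 <- stats::setNames(rep("root", 12), genes)
  P2 <- stats::setNames(rep(c("L1", "L2"), each = 6), genes)
  tree <- reconcile_tree(list(P1, P2))
  # identical motif multisets: no signal, must merge
  motif_pool <- withr::with_seed(5, random_motifs(6))
  motifs_same <- stats::setNames(c(motif_pool, motif_pool), genes)
  pruned <- prune_sisters_rf(tree, motifs_same, n_perm = 99, seed = 3)
  expect_length(unique(pruned$layers[[2]]), 1L)
  # leaves differing at every position with distinct residues: never merged
  m1 <- strrep("A", 12)
  m2 <- strrep("K", 12)
  motifs_diff <- stats::setNames(
    c(rep(m1, 6), rep(m2, 6)), genes
  )
  kept <- prune_sisters_rf(tree, motifs_diff, n_perm = 99, seed = 4)
  expect_length(unique(kept$layers[[2]]), 2L)
  # alpha = 1: degenerate threshold merges every pair
  merged <- prune_sisters_rf(tree, motifs_diff, n_perm = 19, alpha = 1,
    seed = 5
  )
  expect_length(unique(merged$layers[[2]]), 1L)
  expect_true(pepfam:::tree_is_nested(merged))
})

test_that("polytomy resolution prefers the low-entropy merge and is optimal", {
  # two all-glycine children and one all-serine at a position: G children
  # merge first (enumerate the 3 rooted shapes by exhaustive search)
  ch <- list(
    c1 = c("GGGG", "GGGG"), c2 = c("GGGG", "GGGG"),
    c3 = c("SSSS", "SSSS")
  )
  res <- resolve_polytomy_entropy(ch)
  expect_equal(res$method, "exhaustive")
  expect_equal(res$newick, "((c1,c2),c3);")
  greedy <- resolve_polytomy_entropy(ch, method = "greedy")
  expect_equal(greedy$objective, res$objective)
  # identical compositions: all topologies tie, output deterministic
  same <- list(a = c("AC", "CA"), b = c("AC", "CA"), c = c("CA", "AC"))
  r1 <- resolve_polytomy_entropy(same)
  r2 <- resolve_polytomy_entropy(same)
  expect_identical(r1$newick, r2$newick)
  # greedy objective is never better than the exhaustive optimum (m = 6)
  withr::with_seed(11, {
    for (rep in 1:5) {
      ch6 <- lapply(1:6, function(i) random_motifs(3, L = 6))
      names(ch6) <- paste0("k", 1:6)
      ex <- resolve_polytomy_entropy(ch6, method = "exhaustive")
      gr <- resolve_polytomy_entropy(ch6, method = "greedy")
      expect_gte(gr$objective + 1e-9, ex$objective)
    }
  })
  expect_error(resolve_polytomy_entropy(same[1:2]), "3 children")
})

test_that("hierarchy newick serialization is parseable with labeled nodes", {
  genes <- paste0("g", 1:6)
  P1 <- stats::setNames(rep(c("A", "B"), each = 3), genes)
  P2 <- stats::setNames(c("x", "x", "y", "z", "z", "w"), genes)
  tr <- reconcile_tree(list(P1, P2))
  nwk <- hierarchy_newick(tr, genes_as_leaves = TRUE)
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, genes)
})
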