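random_promoter <- function(n, seed) {
  withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE),
    collapse = ""
  ))
}

test_that("promoter similarity has the containment-Jaccard identities", {
  p <- random_promoter(300, 1)
  expect_equal(promoter_similarity(p, p), 1)
  # disjoint alphabet halves share no k-mer (and no canonical collision:
  # AC-only k-mers reverse-complement into GT-only k-mers)
  a <- strrep("AACC", 30)
  b <- strrep("TTAA", 30)
  expect_equal(promoter_similarity(a, b, k = 8), 0)
  expect_error(promoter_similarity("ACGT", p, k = 12), "shorter")
})

test_that("containment stays ~1 for a half-promoter while plain Jaccard halves", {
  p <- random_promoter(400, 7)
  half <- substr(p, 1, 200)
  k <- 12
  ka <- pepfam:::canonical_kmers(p, k)
  kb <- pepfam:::canonical_kmers(half, k)
  containment <- length(intersect(ka, kb)) / min(length(ka), length(kb))
  jaccard <- length(intersect(ka, kb)) / length(union(ka, kb))
  expect_equal(promoter_similarity(p, half, k), containment)
  expect_equal(containment, 1)
  expect_lt(jaccard, 0.6)
  expect_gt(jaccard, 0.4)
})

test_that("promoter network mirrors planted erosion structure", {
  mk_fam <- function(erosion, seed) {
    generate_family(family_sim_config(
      n_clades = 2, genes_per_clade = 5, erosion_asymmetry = erosion,
      duplication_events = 2, seed = seed
    ))
  }
  fam0 <- mk_fam(0, 31)
  net0 <- build_promoter_network(fam0$genes, min_sim = 0)
  pp0 <- fam0$truth$paralog_pairs
  sim_of <- function(net, a, b) {
    e <- net$edges
    hit <- (e$from == a & e$to == b) | (e$from == b & e$to == a)
    if (any(hit)) e$weight[hit] else 0
  }
  sims0 <- mapply(sim_of, list(net0), pp0$gene_a, pp0$gene_b)
  # intact shared block + shared background (1% background divergence)
  expect_true(all(sims0 > 0.75))
  fam5 <- mk_fam(0.5, 31)
  net5 <- build_promoter_network(fam5$genes, min_sim = 0)
  sims5 <- mapply(sim_of, list(net5), fam5$truth$paralog_pairs$gene_a,
    fam5$truth$paralog_pairs$gene_b
  )
  expect_true(all(sims5 < min(sims0))) # erosion strictly lowers similarity
  # min_sim above 1 leaves no edges
  net_empty <- build_promoter_network(fam0$genes, min_sim = 1 + 1e-9)
  expect_equal(nrow(net_empty$edges), 0L)
  # genes without usable promoters are excluded with a warning
  broken <- fam0$genes
  broken$promoter[1] <- ""
  expect_warning(build_promoter_network(broken, min_sim = 0), "Excluding")
})

test_that("label propagation fills components from their seeds and clamps", {
  e <- tibble::tibble(
    from = c("a1", "a2", "b1", "b2"),
    to = c("a2", "a3", "b2", "b3"), weight = 1
  )
  g <- make_graph(e)
  st <- propagate_labels(g, c(a1 = "left", b1 = "right"))
  expect_equal(
    stats::setNames(st$label, st$gene_id),
    c(a1 = "left", a2 = "left", a3 = "left",
      b1 = "right", b2 = "right", b3 = "right")
  )
  expect_true(all(st$confidence[st$seeded] == 1))
  # all nodes seeded: output equals input
  seeds_all <- stats::setNames(paste0("s", 1:6), sort(g$nodes))
  st2 <- propagate_labels(g, seeds_all)
  expect_equal(stats::setNames(st2$label, st2$gene_id), seeds_all)
  expect_error(propagate_labels(g, character()), "seed")
})

test_that("propagation matches the brute-force fixed point on barbell graphs", {
  # two triangles joined by a path; bridge nodes go to the heavier side
  e <- tibble::tibble(
    from = c("a1", "a1", "a2", "b1", "b1", "b2", "a3", "m", "m"),
    to = c("a2", "a3", "a3", "b2", "b3", "b3", "m", "b3", "a1"),
    weight = c(1, 1, 1, 1, 1, 1, 2.0, 0.5, 0.1)
  )
  g <- make_graph(e)
  seeds <- c(a1 = "A", b1 = "B")
  st <- propagate_labels(g, seeds)
  W <- pepfam:::graph_adjacency(g)
  oracle <- lp_oracle(W, seeds)
  expect_equal(stats::setNames(st$label, st$gene_id), oracle[st$gene_id])
  expect_equal(st$label[st$gene_id == "m"], "A") # nearer/heavier side
})

test_that("propagation is equivariant under node relabeling", {
  withr::with_seed(19, {
    n <- 9
    pairs <- t(utils::combn(n, 2))
    keep <- runif(nrow(pairs)) < 0.4
    e <- tibble::tibble(
      from = paste0("n", pairs[keep, 1]),
      to = paste0("n", pairs[keep, 2]),
      weight = round(runif(sum(keep), 0.5, 2), 2)
    )
  })
  g <- make_graph(e, nodes = paste0("n", 1:9))
  seeds <- c(n1 = "X", n9 = "Y")
  st <- propagate_labels(g, seeds)
  # relabel nodes by an arbitrary permutation
  perm <- stats::setNames(paste0("m", c(4, 2, 9, 7, 5, 3, 1, 8, 6)),
    paste0("n", 1:9)
  )
  e2 <- tibble::tibble(
    from = perm[e$from], to = perm[e$to], weight = e$weight
  )
  g2 <- make_graph(e2, nodes = unname(perm))
  st2 <- propagate_labels(g2, stats::setNames(seeds, perm[names(seeds)]))
  lab1 <- stats::setNames(st$label, perm[st$gene_id])
  lab2 <- stats::setNames(st2$label, st2$gene_id)
  expect_equal(lab1[sort(names(lab1))], lab2[sort(names(lab2))])
})

test_that("paralog groups recover planted pairs at noiseless settings", {
  fam <- generate_family(family_sim_config(
    n_clades = 3, genes_per_clade = 6, erosion_asymmetry = 0,
    duplication_events = 3, seed = 23
  ))
  g <- fam$genes
  net <- prune_top_k(build_graph(g), 20)
  emb <- embed_walks(
    random_walks(net, walk_config(seed = 2)),
    dims = 16, context_window = 10
  )
  knn <- knn_graph(emb, 5)
  pn <- build_promoter_network(g, min_sim = 0.1)
  groups <- assign_paralog_groups(g, knn, pn, sim_seed_threshold = 0.5)
  gmap <- stats::setNames(groups$group, groups$gene_id)
  pp <- fam$truth$paralog_pairs
  expect_true(all(gmap[pp$gene_a] == gmap[pp$gene_b]))
  # planted pairs form their own groups: no outsider shares their label
  pair_groups <- gmap[pp$gene_a]
  outsiders <- setdiff(g$gene_id, c(pp$gene_a, pp$gene_b))
  expect_false(any(gmap[outsiders] %in% pair_groups))
  # a threshold above every similarity seeds singletons only
  singles <- assign_paralog_groups(g, knn, pn, sim_seed_threshold = 1.01)
  expect_equal(length(unique(singles$group)), nrow(g))
})
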