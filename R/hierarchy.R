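# Multi-resolution community detection, reconciliation into a strictly nested
# tree, random-forest permutation pruning of sister leaves, and
# entropy-minimizing polytomy resolution.

#' Constant-Potts-model partition quality
#'
#' `Q(P; gamma) = sum_c [ w_in(c) - gamma * n_c (n_c - 1) / 2 ]` where
#' `w_in(c)` is the total weight of edges inside community `c`.
#'
#' @param graph a `sim_graph`.
#' @param membership named vector (gene_id -> community id).
#' @param gamma resolution parameter.
#' @return single numeric quality.
#' @export
cpm_quality <- function(graph, membership, gamma) {
  e <- graph$edges
  within <- membership[e$from] == membership[e$to]
  w_in <- sum(e$weight[within])
  sizes <- table(membership[graph$nodes])
  w_in - gamma * sum(sizes * (sizes - 1) / 2)
}

#' Multi-resolution Leiden community detection (CPM objective)
#'
#' Runs the Leiden algorithm with the constant Potts model objective at each
#' resolution, with several seeded restarts per resolution, keeping the
#' best-quality partition. Leiden guarantees connected communities.
#'
#' @param graph a `sim_graph`.
#' @param resolutions ascending vector of CPM resolution parameters. The
#'   default is a geometric ladder of 6 values spanning the observed edge
#'   weights.
#' @param n_restarts Leiden restarts per resolution (best kept).
#' @param seed integer seed for tie-breaking.
#' @return list of partitions: tibbles `(gene_id, community)` with attribute
#'   `resolution`.
#' @export
multires_communities <- function(graph, resolutions = NULL, n_restarts = 10,
                                 seed = 1) {
  if (is.null(resolutions)) {
    w <- graph$edges$weight
    if (length(w) == 0L) {
      resolutions <- 1
    } else {
      resolutions <- exp(seq(log(max(mean(w) / 50, 1e-6)),
        log(max(w) * 1.5),
        length.out = 6
      ))
    }
  }
  if (length(resolutions) < 1L) abort("Need at least one resolution.")
  if (is.unsorted(resolutions)) abort("Resolutions must be ascending.")
  g <- igraph::graph_from_data_frame(graph$edges[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = graph$nodes)
  )
  weights <- graph$edges$weight
  withr::with_seed(seed, {
    lapply(resolutions, function(gamma) {
      best <- NULL
      best_q <- -Inf
      for (r in seq_len(n_restarts)) {
        cl <- igraph::cluster_leiden(
          g,
          objective_function = "CPM", weights = weights,
          resolution = gamma, n_iterations = 10
        )
        memb <- setNames(igraph::membership(cl), igraph::V(g)$name)
        q <- cpm_quality(graph, memb, gamma)
        if (q > best_q + 1e-12) {
          best_q <- q
          best <- memb
        }
      }
      out <- tibble(
        gene_id = names(best),
        community = as.integer(best[names(best)])
      )
      attr(out, "resolution") <- gamma
      attr(out, "quality") <- best_q
      out
    })
  })
}

# ---------------------------------------------------------------------------
# Tree reconciliation: strictly nested layers minimizing total membership
# reassignments relative to the input partitions. Alternating optimization:
# (a) plurality-containment lift of cluster parents, (b) per-gene path
# reassignment, iterated to convergence.

partition_to_named <- function(p) {
  if (is.data.frame(p)) {
    setNames(as.character(p$community), p$gene_id)
  } else {
    setNames(as.character(p), names(p))
  }
}

#' Reconcile multi-resolution partitions into a nested hierarchy
#'
#' Input partitions (ordered coarse to fine) need not be mutually nested; the
#' output layers are strictly nested and minimize the number of per-gene,
#' per-layer membership changes relative to the inputs. The finest layer
#' seeds the leaf assignment; parents are lifted by plurality containment and
#' genes are then reassigned to the leaf path with the fewest disagreements,
#' alternating until the total cost stops improving.
#'
#' @param partitions list of partitions from [multires_communities()] (or any
#'   list of tibbles `(gene_id, community)` / named vectors), coarse first.
#' @return a `hierarchy_tree`: list with `layers` (list of named
#'   character vectors gene -> cluster label, coarse to fine, root layer
#'   implicit), `parent` maps between consecutive layers, and
#'   `n_reassignments`.
#' @export
reconcile_tree <- function(partitions) {
  if (length(partitions) == 0L) abort("Empty partition list.")
  P <- lapply(partitions, partition_to_named)
  genes <- names(P[[1]])
  for (p in P) {
    if (!setequal(names(p), genes)) {
      abort("All partitions must cover the same genes.")
    }
  }
  P <- lapply(P, function(p) p[genes])
  L <- length(P)
  if (L == 1L) {
    layers <- list(`1` = P[[1]])
    return(new_hierarchy_tree(layers, 0L))
  }
  leaf <- P[[L]]
  state <- lift_parents(leaf, P)
  cost <- state$cost
  for (iter in seq_len(100L)) {
    leaf2 <- reassign_genes(state, P)
    state2 <- lift_parents(leaf2, P)
    if (state2$cost >= cost) break
    state <- state2
    cost <- state2$cost
  }
  layers <- state$layers
  names(layers) <- as.character(seq_len(L))
  new_hierarchy_tree(layers, cost)
}

# Given a leaf assignment, lift parents by plurality containment; returns
# layers (coarse->fine), per-leaf label paths, and total reassignment cost.
lift_parents <- function(leaf, P) {
  L <- length(P)
  genes <- names(P[[1]])
  layers <- vector("list", L)
  layers[[L]] <- leaf
  # path[lab, l]: label at layer l of the path through leaf cluster `lab`
  leaf_labs <- sort(unique(leaf))
  path <- matrix(NA_character_, length(leaf_labs), L,
    dimnames = list(leaf_labs, NULL)
  )
  path[, L] <- leaf_labs
  cur <- leaf
  for (l in seq(L - 1L, 1L)) {
    parent <- vapply(leaf_labs, function(lab) {
      members <- genes[cur == lab]
      tab <- sort(table(P[[l]][members]), decreasing = TRUE)
      names(tab)[1]
    }, character(1))
    # plurality lift is per current-layer cluster chain: group leaf labels
    # that already share a parent path above
    path[, l] <- parent[leaf_labs]
    layers[[l]] <- setNames(parent[cur], genes)
  }
  # enforce nestedness across non-adjacent layers: identical label at layer l
  # but different at l-1 would break the partition property; disambiguate by
  # prefixing labels with their full ancestor path
  for (l in seq_len(L)) {
    if (l == 1L) next
    pref <- layers[[l - 1L]]
    layers[[l]] <- setNames(paste(pref, layers[[l]], sep = "|"), genes)
  }
  cost <- 0L
  for (l in seq_len(L)) {
    out_l <- strip_prefix(layers[[l]])
    cost <- cost + sum(out_l != P[[l]])
  }
  list(layers = layers, cost = cost, leaf = leaf)
}

strip_prefix <- function(lab) {
  vapply(strsplit(lab, "|", fixed = TRUE), function(x) x[length(x)],
    character(1),
    USE.NAMES = FALSE
  )
}

# Reassign each gene to the leaf path minimizing its total disagreement with
# the input partitions (tie -> keep current, then lexicographic path label).
reassign_genes <- function(state, P) {
  L <- length(P)
  genes <- names(P[[1]])
  leaf_paths <- unique(state$layers[[L]])
  # layer labels along each candidate path (strip to input labels)
  path_mat <- vapply(seq_len(L), function(l) {
    lab_l <- state$layers[[l]]
    lab_l[match(leaf_paths, state$layers[[L]])]
  }, character(length(leaf_paths)))
  path_mat <- matrix(path_mat, nrow = length(leaf_paths))
  path_stripped <- apply(path_mat, 2, strip_prefix)
  path_stripped <- matrix(path_stripped, nrow = length(leaf_paths))
  new_leaf <- state$leaf
  for (gidx in seq_along(genes)) {
    g <- genes[gidx]
    targets <- vapply(seq_len(L), function(l) P[[l]][[g]], character(1))
    cost_g <- rowSums(path_stripped != matrix(targets,
      nrow = nrow(path_stripped), ncol = L, byrow = TRUE
    ))
    cur_path <- state$layers[[L]][[g]]
    best <- min(cost_g)
    cands <- leaf_paths[cost_g == best]
    pick <- if (cur_path %in% cands) cur_path else sort(cands)[1]
    new_leaf[[g]] <- state$leaf[match(pick, state$layers[[L]])][[1]]
  }
  new_leaf
}

new_hierarchy_tree <- function(layers, n_reassignments) {
  genes <- names(layers[[1]])
  structure(
    list(
      layers = layers,
      n_reassignments = as.integer(n_reassignments),
      genes = genes
    ),
    class = "hierarchy_tree"
  )
}

#' @export
print.hierarchy_tree <- function(x, ...) {
  sizes <- vapply(x$layers, function(l) length(unique(l)), integer(1))
  cat(sprintf(
    "<hierarchy_tree> %d genes, %d levels (clusters per level: %s), %d reassignments\n",
    length(x$genes), length(x$layers), paste(sizes, collapse = " "),
    x$n_reassignments
  ))
  invisible(x)
}

# Validate the nestedness invariant: children partition their parent.
tree_is_nested <- function(tree) {
  L <- length(tree$layers)
  if (L < 2L) {
    return(TRUE)
  }
  for (l in 2:L) {
    tab <- table(tree$layers[[l]], tree$layers[[l - 1L]])
    if (any(rowSums(tab > 0) > 1L)) {
      return(FALSE)
    }
  }
  TRUE
}

# ---------------------------------------------------------------------------
# Random-forest permutation pruning of sister leaves.

one_hot_motifs <- function(motifs) {
  M <- seqs_to_matrix(motifs)
  cols <- lapply(seq_len(ncol(M)), function(p) {
    res <- sort(unique(M[, p]))
    oh <- matrix(0L, nrow(M), length(res),
      dimnames = list(NULL, paste0("p", p, res))
    )
    oh[cbind(seq_len(nrow(M)), match(M[, p], res))] <- 1L
    oh
  })
  do.call(cbind, cols)
}

rf_oob_accuracy <- function(X, y, num_trees, seed) {
  df <- as.data.frame(X)
  df$.y <- factor(y)
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = num_trees, classification = TRUE,
    num.threads = 1, seed = seed
  )
  1 - fit$prediction.error
}

#' Permutation test of sister-leaf separability
#'
#' Trains a random forest to separate two sets of 12-residue motifs using
#' one-hot position encodings and compares the out-of-bag accuracy with a
#' null distribution obtained by permuting the leaf labels. The p-value
#' follows the `(1 + #null >= observed) / (n_perm + 1)` convention.
#'
#' @param motifs_a,motifs_b character vectors of equal-length motifs.
#' @param n_perm permutations (default 199).
#' @param num_trees forest size (default 100).
#' @param seed integer seed.
#' @return list with `observed` accuracy, `null` accuracies, `p_value` and
#'   `threshold_quantile` helper.
#' @export
sister_separation_test <- function(motifs_a, motifs_b, n_perm = 199,
                                   num_trees = 100, seed = 1) {
  y <- c(rep("a", length(motifs_a)), rep("b", length(motifs_b)))
  X <- one_hot_motifs(c(motifs_a, motifs_b))
  withr::with_seed(seed, {
    obs <- rf_oob_accuracy(X, y, num_trees, seed = sample.int(1e6, 1))
    null <- vapply(seq_len(n_perm), function(r) {
      rf_oob_accuracy(X, sample(y), num_trees, seed = sample.int(1e6, 1))
    }, numeric(1))
    list(
      observed = obs, null = null,
      p_value = (1 + sum(null >= obs)) / (n_perm + 1)
    )
  })
}

# merge decision: keep the split only when observed accuracy exceeds the
# (1 - alpha) null quantile (k-th smallest, k = ceiling((1-alpha) * n_perm)).
# alpha = 1 is degenerate: the null threshold vanishes and every pair merges.
merge_decision <- function(test, alpha, n_perm) {
  k <- ceiling((1 - alpha) * n_perm)
  if (k <= 0) {
    return(TRUE)
  }
  test$observed <= sort(test$null)[k]
}

#' Prune indistinguishable sister leaves from a hierarchy
#'
#' For every pair of sister leaves (leaves sharing a parent), a random-forest
#' permutation test ([sister_separation_test()]) checks whether the two leaf
#' motif sets are separable. Pairs that fail (observed out-of-bag accuracy at
#' or below the `1 - alpha` null quantile) are merged; passes repeat until no
#' pair merges. Leaves with fewer than 2 members are merged into their sister
#' with a logged note (untrainable).
#'
#' @param tree a `hierarchy_tree`.
#' @param motifs named character vector gene_id -> 12-residue motif.
#' @param n_perm permutations per test (default 199).
#' @param alpha significance level (default 0.05).
#' @param num_trees forest size (default 100).
#' @param seed integer seed.
#' @return pruned `hierarchy_tree` (leaf layer updated).
#' @export
prune_sisters_rf <- function(tree, motifs, n_perm = 199, alpha = 0.05,
                             num_trees = 100, seed = 1) {
  if (!all(tree$genes %in% names(motifs))) {
    abort("Every gene in the tree needs a motif.")
  }
  L <- length(tree$layers)
  leaf <- tree$layers[[L]]
  parent <- if (L >= 2L) tree$layers[[L - 1L]] else
    setNames(rep("root", length(leaf)), names(leaf))
  seed_i <- seed
  repeat {
    merged <- FALSE
    leaves_by_parent <- split(
      unique(data.frame(leaf = leaf, parent = parent))$leaf,
      unique(data.frame(leaf = leaf, parent = parent))$parent
    )
    for (sibs in leaves_by_parent) {
      sibs <- sort(sibs)
      if (length(sibs) < 2L) next
      for (pair in utils::combn(sibs, 2, simplify = FALSE)) {
        g1 <- names(leaf)[leaf == pair[1]]
        g2 <- names(leaf)[leaf == pair[2]]
        if (length(g1) == 0L || length(g2) == 0L) next
        if (length(g1) < 2L || length(g2) < 2L) {
          inform(sprintf(
            "Leaf pair (%s, %s) auto-merged: a leaf has < 2 members.",
            pair[1], pair[2]
          ))
          do_merge <- TRUE
        } else {
          tst <- sister_separation_test(
            motifs[g1], motifs[g2],
            n_perm = n_perm, num_trees = num_trees, seed = seed_i
          )
          seed_i <- seed_i + 1L
          do_merge <- merge_decision(tst, alpha, n_perm)
        }
        if (do_merge) {
          leaf[leaf == pair[2]] <- pair[1]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  tree$layers[[L]] <- leaf
  tree
}

# ---------------------------------------------------------------------------
# Entropy-minimizing polytomy resolution.

# member-weighted positional entropy cost of a set of motifs: n * sum_p H_p
motif_entropy_cost <- function(motifs) {
  M <- seqs_to_matrix(motifs)
  H <- vapply(seq_len(ncol(M)), function(p) {
    f <- table(M[, p]) / nrow(M)
    -sum(f * log(f))
  }, numeric(1))
  nrow(M) * sum(H)
}

#' Resolve a polytomy by parsimonious entropy minimization
#'
#' Pairs the `m >= 3` children of a node into a binary subtree so that the
#' total member-weighted positional Shannon entropy of the merged residue
#' distributions is minimal: exhaustive dynamic programming over subsets for
#' `m <= 6` children, greedy agglomeration (each merge minimizes the entropy
#' increase) beyond. Ties break deterministically by child id.
#'
#' @param children named list: child id -> character vector of member motifs.
#' @param method `"auto"` (exhaustive for `m <= 6`), `"exhaustive"`, or
#'   `"greedy"`.
#' @return list with `merges` (nested-list binary tree of child ids, printed
#'   as newick in `newick`), `objective` (sum of internal-node entropy
#'   costs), and `method`.
#' @export
resolve_polytomy_entropy <- function(children, method = c(
                                       "auto", "exhaustive", "greedy"
                                     )) {
  method <- match.arg(method)
  m <- length(children)
  if (m < 3L) abort("Need at least 3 children.")
  if (is.null(names(children))) names(children) <- as.character(seq_len(m))
  children <- children[order(names(children))]
  if (method == "auto") method <- if (m <= 6L) "exhaustive" else "greedy"
  res <- if (method == "exhaustive") {
    polytomy_exhaustive(children)
  } else {
    polytomy_greedy(children)
  }
  res$method <- method
  res$newick <- paste0(tree_to_newick(res$merges), ";")
  res
}

polytomy_greedy <- function(children) {
  items <- lapply(names(children), function(nm) {
    list(tree = nm, motifs = children[[nm]], id = nm)
  })
  objective <- 0
  while (length(items) > 1L) {
    best <- NULL
    best_inc <- Inf
    for (i in seq_len(length(items) - 1L)) {
      for (j in (i + 1L):length(items)) {
        inc <- motif_entropy_cost(c(items[[i]]$motifs, items[[j]]$motifs)) -
          motif_entropy_cost(items[[i]]$motifs) -
          motif_entropy_cost(items[[j]]$motifs)
        key <- sort(c(items[[i]]$id, items[[j]]$id))
        if (inc < best_inc - 1e-12 ||
          (abs(inc - best_inc) <= 1e-12 && !is.null(best) &&
            paste(key, collapse = "") <
              paste(sort(c(items[[best[1]]]$id, items[[best[2]]]$id)),
                collapse = ""
              ))) {
          best_inc <- inc
          best <- c(i, j)
        }
      }
    }
    i <- best[1]
    j <- best[2]
    merged <- list(
      tree = list(items[[i]]$tree, items[[j]]$tree),
      motifs = c(items[[i]]$motifs, items[[j]]$motifs),
      id = min(items[[i]]$id, items[[j]]$id)
    )
    objective <- objective +
      motif_entropy_cost(merged$motifs)
    items <- c(items[-c(i, j)], list(merged))
  }
  list(merges = items[[1]]$tree, objective = objective)
}

# exhaustive: DP over subsets; value(S) = min over splits of
# value(A) + value(S\A) + cost(S)
polytomy_exhaustive <- function(children) {
  m <- length(children)
  ids <- names(children)
  cost <- function(bits) {
    motif_entropy_cost(unlist(children[bits], use.names = FALSE))
  }
  nsub <- 2^m - 1
  val <- rep(NA_real_, nsub)
  tr <- vector("list", nsub)
  subset_bits <- function(s) which(bitwAnd(s, 2^(seq_len(m) - 1L)) > 0)
  for (s in seq_len(nsub)) {
    bits <- subset_bits(s)
    if (length(bits) == 1L) {
      val[s] <- 0
      tr[[s]] <- ids[bits]
      next
    }
    c_s <- cost(bits)
    best <- Inf
    best_tr <- NULL
    # iterate proper sub-splits; canonical: subset containing lowest bit
    low <- 2^(bits[1] - 1L)
    rest <- s - low
    a <- rest
    repeat {
      sub <- a + low
      other <- s - sub
      if (other > 0) {
        v <- val[sub] + val[other] + c_s
        if (v < best - 1e-12) {
          best <- v
          best_tr <- list(tr[[sub]], tr[[other]])
        }
      }
      if (a == 0) break
      a <- bitwAnd(a - 1, rest)
    }
    val[s] <- best
    tr[[s]] <- best_tr
  }
  list(merges = tr[[nsub]], objective = val[nsub])
}

tree_to_newick <- function(tr) {
  if (is.character(tr)) {
    return(tr)
  }
  paste0("(", tree_to_newick(tr[[1]]), ",", tree_to_newick(tr[[2]]), ")")
}

#' Serialize a hierarchy tree as Newick with level/cluster labels
#'
#' Internal nodes are labeled `L<level>_C<index>`; leaves are the finest
#' clusters with their member counts, or individual genes when
#' `genes_as_leaves = TRUE`.
#'
#' @param tree a `hierarchy_tree`.
#' @param genes_as_leaves expand leaf clusters into their member genes.
#' @return single newick string.
#' @export
hierarchy_newick <- function(tree, genes_as_leaves = FALSE) {
  L <- length(tree$layers)
  labmap <- lapply(tree$layers, function(lay) {
    sort(unique(lay))
  })
  build <- function(level, cluster) {
    members <- names(tree$layers[[level]])[tree$layers[[level]] == cluster]
    idx <- match(cluster, labmap[[level]])
    node_lab <- sprintf("L%d_C%d", level, idx)
    if (level == L) {
      if (genes_as_leaves) {
        if (length(members) == 1L) {
          return(members)
        }
        return(paste0(
          "(", paste(sort(members), collapse = ","), ")", node_lab
        ))
      }
      return(node_lab)
    }
    kids <- sort(unique(tree$layers[[level + 1L]][members]))
    if (length(kids) == 1L) {
      return(build(level + 1L, kids))
    }
    paste0(
      "(", paste(vapply(kids, function(k) build(level + 1L, k), character(1)),
        collapse = ","
      ), ")", node_lab
    )
  }
  roots <- sort(unique(tree$layers[[1]]))
  if (length(roots) == 1L) {
    paste0(build(1L, roots), ";")
  } else {
    paste0(
      "(", paste(vapply(roots, function(r) build(1L, r), character(1)),
        collapse = ","
      ), ")root;"
    )
  }
}
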