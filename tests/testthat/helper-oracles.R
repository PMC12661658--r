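# Independent oracles used to check pipeline operations. These deliberately
# use naive/brute-force strategies and share no code with the implementation.

aa20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# --- Smith-Waterman affine-gap DP (three-state, O(nm)) ------------------------
sw_oracle <- function(a, b, S = blosum62, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  M <- matrix(-Inf, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0
  M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      M[i, j] <- max(
        0,
        max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) +
          S[A[i - 1], B[j - 1]]
      )
      best <- max(best, M[i, j], Ix[i, j], Iy[i, j])
    }
  }
  best
}

# --- set partitions of n elements (list of integer label vectors) -------------
enumerate_partitions <- function(n) {
  if (n == 1L) {
    return(list(1L))
  }
  out <- list()
  for (p in enumerate_partitions(n - 1L)) {
    k <- max(p)
    for (lab in seq_len(k + 1L)) {
      out[[length(out) + 1L]] <- c(p, lab)
    }
  }
  out
}

# exhaustive CPM optimum over all partitions of a small graph
cpm_oracle <- function(graph, gamma) {
  nodes <- graph$nodes
  n <- length(nodes)
  best_q <- -Inf
  best <- NULL
  for (p in enumerate_partitions(n)) {
    memb <- stats::setNames(p, nodes)
    q <- cpm_quality(graph, memb, gamma)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- memb
    }
  }
  list(membership = best, quality = best_q)
}

# small helper: build a sim_graph from an edge data frame
make_graph <- function(edges, nodes = NULL) {
  nodes <- nodes %||% sort(unique(c(edges$from, edges$to)))
  pepfam:::new_sim_graph(nodes, edges)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

random_small_graph <- function(n, seed, p = 0.5) {
  withr::with_seed(seed, {
    pairs <- t(utils::combn(n, 2))
    keep <- runif(nrow(pairs)) < p
    if (!any(keep)) keep[1] <- TRUE
    make_graph(
      tibble::tibble(
        from = paste0("n", pairs[keep, 1]),
        to = paste0("n", pairs[keep, 2]),
        weight = round(runif(sum(keep), 0.5, 3), 2)
      ),
      nodes = paste0("n", seq_len(n))
    )
  })
}

# --- codon pathway enumeration (independent recursion) ------------------------
codon_pathways_oracle <- function(c1, c2) {
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  dpos <- which(ch1 != ch2)
  if (length(dpos) == 0L) {
    return(c(sd = 0, nd = 0))
  }
  perms <- function(v) {
    if (length(v) <= 1L) {
      return(list(v))
    }
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  res <- list()
  for (ord in perms(dpos)) {
    cur <- ch1
    sd <- 0
    nd <- 0
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- ch2[p]
      aa1 <- gc[paste(cur, collapse = "")]
      aa2 <- gc[paste(nxt, collapse = "")]
      if (aa2 == "*" || aa1 == "*") {
        ok <- FALSE
        break
      }
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) res[[length(res) + 1L]] <- c(sd = sd, nd = nd)
  }
  if (length(res) == 0L) {
    return(NULL)
  }
  colMeans(do.call(rbind, res))
}

# --- synchronous label-propagation fixed point (dense, naive) -----------------
lp_oracle <- function(W, seeds, max_iter = 200) {
  nodes <- rownames(W)
  labs <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  labs[names(seeds)] <- as.character(seeds)
  clamped <- nodes %in% names(seeds)
  step <- function(labs, force = FALSE) {
    out <- labs
    for (v in nodes[!clamped]) {
      wts <- W[v, ]
      ok <- wts > 0 & !is.na(labs)
      if (!any(ok)) next
      votes <- tapply(wts[ok], labs[ok], sum)
      top <- sort(names(votes)[votes >= max(votes) - 1e-12])
      out[v] <- if (length(top) == 1L || force) top[1] else NA_character_
    }
    out
  }
  for (i in seq_len(max_iter)) {
    nxt <- step(labs)
    if (identical(nxt, labs)) break
    labs <- nxt
  }
  step(labs, force = TRUE)
}

# --- central finite differences ----------------------------------------------
fd_gradient <- function(f, p, eps = 1e-5) {
  vapply(seq_along(p), function(i) {
    up <- p
    dn <- p
    up[i] <- up[i] + eps
    dn[i] <- dn[i] - eps
    (f(up) - f(dn)) / (2 * eps)
  }, numeric(1))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

random_motifs <- function(n, L = 12, alphabet = aa20) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
}

# --- minimum-reassignment nested tree, brute force (two layers) ---------------
# Enumerates every leaf-assignment function (over the fine labels) and every
# parent map (fine label -> coarse label); nestedness holds by construction.
reconcile_oracle_2layer <- function(P1, P2) {
  genes <- names(P1)
  labs1 <- sort(unique(P1))
  labs2 <- sort(unique(P2))
  k1 <- length(labs1)
  k2 <- length(labs2)
  n <- length(genes)
  best <- Inf
  leaf_assign <- rep(1L, n)
  repeat {
    parent <- rep(1L, k2)
    repeat {
      cost <- sum(labs2[leaf_assign] != P2) +
        sum(labs1[parent[leaf_assign]] != P1)
      if (cost < best) best <- cost
      # increment parent map
      i <- 1L
      while (i <= k2) {
        parent[i] <- parent[i] + 1L
        if (parent[i] <= k1) break
        parent[i] <- 1L
        i <- i + 1L
      }
      if (i > k2) break
    }
    # increment leaf assignment
    i <- 1L
    while (i <= n) {
      leaf_assign[i] <- leaf_assign[i] + 1L
      if (leaf_assign[i] <= k2) break
      leaf_assign[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
  }
  best
}
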