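# Graph vectorization by biased random walks + shifted-PPMI factorization,
# kNN graph construction, and a diffusion-based 2D projection.
#
# The skip-gram of node2vec is replaced by its closed-form equivalent
# (walk co-occurrence counts -> shifted positive PMI -> truncated SVD), which
# is deterministic given the walk corpus and therefore testable.

#' Random-walk configuration
#'
#' Desk-scale defaults (length 80, 20 walks per node, window 10) keep small
#' analyses fast; `paper_scale = TRUE` switches to the heavy settings used for
#' genome-scale families (length 200, 600 walks per node, window 100).
#'
#' @param walk_length steps per walk.
#' @param walks_per_node walks started from every node.
#' @param context_window co-occurrence window in steps (`<= walk_length`).
#' @param return_p,inout_q node2vec bias parameters (1 = unbiased).
#' @param seed integer seed.
#' @param paper_scale use the heavy preset.
#' @return a `walk_config` list.
#' @export
walk_config <- function(walk_length = 80, walks_per_node = 20,
                        context_window = 10, return_p = 1, inout_q = 1,
                        seed = 1, paper_scale = FALSE) {
  if (paper_scale) {
    walk_length <- 200
    walks_per_node <- 600
    context_window <- 100
  }
  cfg <- list(
    walk_length = check_count(walk_length, "walk_length"),
    walks_per_node = check_count(walks_per_node, "walks_per_node"),
    context_window = check_count(context_window, "context_window"),
    return_p = as.numeric(return_p), inout_q = as.numeric(inout_q),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$context_window > cfg$walk_length) {
    abort("context_window must not exceed walk_length.")
  }
  if (cfg$return_p <= 0 || cfg$inout_q <= 0) {
    abort("return_p and inout_q must be positive.")
  }
  structure(cfg, class = "walk_config")
}

#' Second-order biased random walks over a similarity graph
#'
#' node2vec-style walks: the transition probability to a neighbor is
#' proportional to the edge weight, divided by `return_p` for stepping back to
#' the previous node and by `inout_q` for moving outside the previous node's
#' neighborhood. Isolated nodes yield singleton walks.
#'
#' @param graph a `sim_graph`.
#' @param cfg a [walk_config()].
#' @return a `walk_corpus`: integer matrix (walks x steps, NA-padded) with
#'   attribute `nodes` giving the node-id vocabulary.
#' @export
random_walks <- function(graph, cfg = walk_config()) {
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L) abort("Empty graph.")
  A <- graph_adjacency(graph)
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  wts <- lapply(seq_len(n), function(i) A[i, nbrs[[i]]])
  adj <- A > 0
  withr::with_seed(cfg$seed, {
    starts <- rep(seq_len(n), each = cfg$walks_per_node)
    nw <- length(starts)
    walks <- matrix(NA_integer_, nw, cfg$walk_length)
    walks[, 1] <- starts
    alive <- lengths(nbrs)[starts] > 0L
    prev <- rep(NA_integer_, nw)
    for (step in seq_len(cfg$walk_length - 1L)) {
      cur <- walks[, step]
      act <- which(alive)
      if (length(act) == 0L) break
      nxt <- rep(NA_integer_, nw)
      if (step == 1L || (cfg$return_p == 1 && cfg$inout_q == 1)) {
        # first-order: group by current node
        for (v in unique(cur[act])) {
          idx <- act[cur[act] == v]
          nb <- nbrs[[v]]
          nxt[idx] <- nb[sample.int(length(nb), length(idx),
            replace = TRUE, prob = wts[[v]]
          )]
        }
      } else {
        # second-order: group by (previous, current)
        key <- paste(prev[act], cur[act])
        for (kk in unique(key)) {
          idx <- act[key == kk]
          v <- cur[idx[1]]
          p0 <- prev[idx[1]]
          nb <- nbrs[[v]]
          w <- wts[[v]]
          bias <- ifelse(nb == p0, 1 / cfg$return_p,
            ifelse(adj[p0, nb], 1, 1 / cfg$inout_q)
          )
          wb <- w * bias
          nxt[idx] <- nb[sample.int(length(nb), length(idx),
            replace = TRUE, prob = wb
          )]
        }
      }
      prev <- cur
      walks[, step + 1L] <- nxt
    }
    structure(walks, nodes = nodes, class = "walk_corpus")
  })
}

#' Embed a walk corpus by shifted-PPMI factorization
#'
#' Builds symmetric co-occurrence counts within `context_window` steps,
#' applies the positive pointwise-mutual-information transform, and takes a
#' truncated SVD (`U sqrt(S)`). Deterministic given the corpus (component
#' signs are fixed by convention). `dims` larger than the vocabulary is
#' reduced with a warning.
#'
#' @param walks a `walk_corpus` from [random_walks()].
#' @param dims embedding dimensionality (default 128).
#' @param context_window co-occurrence window; defaults to the corpus's
#'   walk-config window of 10 when not supplied.
#' @return a `gene_embedding`: list with `vectors` (nodes x dims matrix,
#'   rownames = gene ids) and `dims`.
#' @export
embed_walks <- function(walks, dims = 128, context_window = 10) {
  nodes <- attr(walks, "nodes")
  n <- length(nodes)
  if (is.null(nodes) || length(walks) == 0L) abort("Empty walk corpus.")
  C <- matrix(0, n, n)
  len <- ncol(walks)
  for (d in seq_len(min(context_window, len - 1L))) {
    a <- as.vector(walks[, seq_len(len - d), drop = FALSE])
    b <- as.vector(walks[, (1L + d):len, drop = FALSE])
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    cnt <- table(factor(a[ok], levels = seq_len(n)),
      factor(b[ok], levels = seq_len(n))
    )
    C <- C + cnt + t(cnt)
  }
  if (dims > n) {
    warn(sprintf("dims reduced from %d to node count %d", dims, n))
    dims <- n
  }
  tot <- sum(C)
  if (tot == 0) {
    # no co-occurrence at all (all-isolated graph): zero vectors
    V <- matrix(0, n, dims, dimnames = list(nodes, NULL))
    return(structure(list(vectors = V, dims = dims), class = "gene_embedding"))
  }
  rs <- rowSums(C)
  pmi <- log(pmax(C, 0) * tot) - log(outer(rs, rs))
  pmi[C == 0] <- -Inf
  ppmi <- pmax(pmi, 0)
  sv <- svd(ppmi, nu = dims, nv = 0)
  V <- sv$u[, seq_len(dims), drop = FALSE] %*%
    diag(sqrt(sv$d[seq_len(dims)]), dims)
  # sign convention: largest-magnitude loading of each component positive
  for (k in seq_len(dims)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  rownames(V) <- nodes
  structure(list(vectors = V, dims = dims), class = "gene_embedding")
}

#' @export
print.gene_embedding <- function(x, ...) {
  cat(sprintf(
    "<gene_embedding> %d nodes x %d dims\n", nrow(x$vectors), x$dims
  ))
  invisible(x)
}

#' k-nearest-neighbor graph on an embedding
#'
#' Each node is connected to its `k` nearest neighbors by Euclidean distance
#' (union-symmetrized); edge weight is `1 / (1 + distance)`.
#'
#' @param emb a `gene_embedding`.
#' @param k neighbors per node (`<` node count).
#' @return a `sim_graph`.
#' @export
knn_graph <- function(emb, k = 10) {
  V <- emb$vectors
  n <- nrow(V)
  k <- check_count(k, "k")
  if (k >= n) abort("k must be smaller than the node count.")
  D <- as.matrix(dist(V))
  edges <- vector("list", n)
  ids <- rownames(V)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    ord <- order(d, names(d))
    sel <- ord[seq_len(k)]
    edges[[i]] <- tibble(
      from = ids[i], to = names(d)[sel],
      weight = 1 / (1 + unname(d[sel]))
    )
  }
  new_sim_graph(ids, dplyr::bind_rows(edges))
}

#' Diffusion-based 2D projection of an embedding
#'
#' PHATE-style potential-of-heat embedding: adaptive-bandwidth Gaussian
#' affinity (alpha-decay kernel, bandwidth = distance to the `knn_bw`-th
#' neighbor), row-normalized Markov matrix, `t`-step diffusion, log-potential
#' distances, classical MDS to two dimensions. `t = "auto"` picks the knee of
#' the von Neumann entropy curve.
#'
#' @param emb a `gene_embedding` with at least 3 nodes.
#' @param t diffusion steps or `"auto"`.
#' @param knn_bw neighbor index used for the adaptive bandwidth (default 5).
#' @param alpha kernel decay exponent (default 2, i.e. Gaussian).
#' @return tibble with `gene_id`, `x`, `y`.
#' @export
project_2d <- function(emb, t = "auto", knn_bw = 5, alpha = 2) {
  V <- emb$vectors
  n <- nrow(V)
  if (n < 3L) abort("Need at least 3 nodes to project.")
  D <- as.matrix(dist(V))
  kth <- min(knn_bw + 1L, n)
  sigma <- apply(D, 1, function(r) sort(r)[kth])
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1e-12)
  K <- exp(-(D / sigma)^alpha)
  K <- (K + t(K)) / 2
  P <- K / rowSums(K)
  if (identical(t, "auto")) {
    t <- vne_knee(P)
  }
  Pt <- matpow(P, t)
  logp <- log(Pt + 1e-12)
  pot <- as.matrix(dist(logp))
  xy <- suppressWarnings(cmdscale(pot, k = 2))
  # degenerate (all-coincident) inputs can yield < 2 positive eigenvalues
  if (ncol(xy) < 2) {
    xy <- cbind(xy, matrix(0, n, 2 - ncol(xy)))
  }
  tibble(gene_id = rownames(V), x = xy[, 1], y = xy[, 2])
}

matpow <- function(P, t) {
  out <- diag(nrow(P))
  base <- P
  while (t > 0) {
    if (t %% 2 == 1) out <- out %*% base
    base <- base %*% base
    t <- t %/% 2
  }
  out
}

# von Neumann entropy knee over t = 1..t_max
vne_knee <- function(P, t_max = 30) {
  ev <- abs(Re(eigen(P, only.values = TRUE)$values))
  ts <- seq_len(t_max)
  H <- vapply(ts, function(t) {
    lam <- ev^t
    lam <- lam / sum(lam)
    lam <- lam[lam > 0]
    -sum(lam * log(lam))
  }, numeric(1))
  # knee: farthest point from the chord between endpoints
  x1 <- ts[1]
  y1 <- H[1]
  x2 <- ts[t_max]
  y2 <- H[t_max]
  d <- abs((y2 - y1) * ts - (x2 - x1) * H + x2 * y1 - y2 * x1)
  ts[which.max(d)]
}
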