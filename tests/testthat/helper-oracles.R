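# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they validate: enumeration instead of log-space sums,
# matrix powers instead of graph library calls, direct step-up arithmetic
# instead of p.adjust.

# Tail P(overlap >= r) by exhaustive enumeration of all n-subsets of an
# m-universe whose first t elements are marked.
enumHyperTail <- function(m, t, n, r) {
  if (n == 0) return(if (r <= 0) 1 else 0)
  subsets <- utils::combn(m, n)
  ov <- colSums(subsets <= t)
  mean(ov >= r)
}

# Degree, betweenness and closeness from an adjacency matrix, using the
# fact that the first power L with (A^L)[s,t] > 0 is the shortest distance
# and its entry counts the shortest paths.
bruteCentralities <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  powers <- vector("list", n)
  Ak <- diag(n)
  for (L in seq_len(n)) {
    Ak <- Ak %*% A
    powers[[L]] <- Ak
    new <- is.infinite(D) & Ak > 0
    D[new] <- L
  }
  sigma <- function(s, t) {
    if (s == t) return(1)
    d <- D[s, t]
    if (!is.finite(d)) return(0)
    powers[[d]][s, t]
  }
  btw <- numeric(n); clo <- numeric(n)
  for (v in seq_len(n)) {
    b <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      d <- D[s, t]
      if (!is.finite(d)) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) && D[s, v] + D[v, t] == d)
        b <- b + sigma(s, v) * sigma(v, t) / sigma(s, t)
    }
    btw[v] <- b
    dv <- D[v, -v]; dv <- dv[is.finite(dv)]
    clo[v] <- if (length(dv)) 1 / sum(dv) else 0
  }
  list(degree = rowSums(A), betweenness = btw, closeness = clo)
}

# Step-up BH adjustment from the definition.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# All-pairs average-linkage agglomeration on a distance matrix; returns the
# sorted merge heights. Average distance between clusters is the mean of
# member pairwise distances.
bruteUPGMAHeights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestv <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      v <- mean(d[clusters[[i]], clusters[[j]]])
      if (v < bestv - 1e-12) { bestv <- v; best <- c(i, j) }
    }
    heights <- c(heights, bestv)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  sort(heights)
}

randomAdjacency <- function(n, p) {
  A <- matrix(0, n, n)
  if (n > 1) {
    up <- which(upper.tri(A))
    A[up] <- as.numeric(stats::runif(length(up)) < p)
    A <- A + t(A)
  }
  A
}

graphFromAdjacency <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- paste0("v", seq_len(nrow(A)))
  g
}

smallConfig <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_mirna = 50, n_lnc = 10, n_mrna = 12,
                   targets_per_gene = 6, n_planted_pairs = 3,
                   planted_overlap = 5, n_hub_lnc = 0, hub_n_mrna = 1,
                   n_samples_per_group = 4)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulationConfig, args)
}
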