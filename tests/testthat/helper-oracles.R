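# Brute-force oracles, deliberately independent of the package's algorithms:
# Floyd-Warshall distances, exhaustive geodesic enumeration, union-find
# components, neighbor-pair counting, dense eigendecomposition, and explicit
# midrank construction. Only meant for small graphs / vectors.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1L] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_density <- function(adj) {
  n <- nrow(adj)
  m <- sum(adj[upper.tri(adj)])
  2 * m / (n^2 - n)
}

oracle_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  idx <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    ri <- find(idx[r, 1L])
    rj <- find(idx[r, 2L])
    if (ri != rj) parent[ri] <- rj
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nbr <- which(adj[i, ] == 1L)
    k <- length(nbr)
    if (k < 2L) next
    links <- 0L
    for (p in utils::combn(nbr, 2L, simplify = FALSE)) {
      if (adj[p[1L], p[2L]] == 1L) links <- links + 1L
    }
    cc[i] <- links / choose(k, 2L)
  }
  mean(cc)
}

oracle_closeness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  out <- numeric(n)
  for (i in seq_len(n)) {
    reach <- which(is.finite(d[i, ]) & seq_len(n) != i)
    if (length(reach) > 0L) out[i] <- 1 / sum(d[i, reach])
  }
  out
}

# all geodesic paths between j and k, by recursive backtracking on distances
all_geodesics <- function(adj, d, j, k) {
  if (!is.finite(d[j, k])) return(list())
  walk <- function(v) {
    if (v == j) return(list(j))
    prevs <- which(adj[, v] == 1L & d[j, ] == d[j, v] - 1)
    out <- list()
    for (u in prevs) {
      for (p in walk(u)) out <- c(out, list(c(p, v)))
    }
    out
  }
  walk(k)
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  b <- numeric(n)
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) {
      paths <- all_geodesics(adj, d, j, k)
      g <- length(paths)
      if (g == 0L) next
      through <- integer(0)
      for (p in paths) through <- c(through, setdiff(p, c(j, k)))
      if (length(through) > 0L) {
        tab <- table(through)
        b[as.integer(names(tab))] <- b[as.integer(names(tab))] + tab / g
      }
    }
  }
  b
}

oracle_eigenvector <- function(adj, tol = 1e-8) {
  n <- nrow(adj)
  if (sum(adj) == 0L) return(numeric(n))
  es <- eigen(adj, symmetric = TRUE)
  lam <- max(es$values)
  space <- es$vectors[, es$values >= lam - tol, drop = FALSE]
  v <- as.vector(space %*% crossprod(space, rep(1, n)))
  v <- abs(v)
  v[v < tol] <- 0
  v / max(v)
}

# midranks by explicit counting; Pearson by the raw sum formula
oracle_spearman_rho <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- midrank(x)
  ry <- midrank(y)
  n <- length(x)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt(n * sum(rx^2) - sum(rx)^2) * sqrt(n * sum(ry^2) - sum(ry)^2)
  num / den
}
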