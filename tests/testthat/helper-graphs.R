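# small adjacency-matrix builders used across index tests

adj_from_edges <- function(n, edges, ids = NULL) {
  a <- matrix(0L, n, n)
  if (length(edges) > 0L) {
    e <- matrix(unlist(edges), ncol = 2L, byrow = TRUE)
    a[e] <- 1L
    a[e[, 2:1, drop = FALSE]] <- 1L
  }
  if (!is.null(ids)) dimnames(a) <- list(ids, ids)
  a
}

complete_graph <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  a
}

path_graph <- function(n) {
  adj_from_edges(n, lapply(seq_len(n - 1L), function(i) c(i, i + 1L)))
}

star_graph <- function(k) {
  # center is vertex 1, k leaves
  adj_from_edges(k + 1L, lapply(seq_len(k), function(i) c(1L, i + 1L)))
}

random_graph <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.integer(stats::runif(length(up)) < p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}
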