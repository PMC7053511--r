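#' @name network_indices
#' @title Network indices
#'
#' @description
#' Global indices (density, number of connected components, clustering
#' coefficient) and vertex centralities (degree, closeness, betweenness,
#' eigenvector) of a binary undirected proximity network, computed from first
#' principles on the adjacency matrix. Conventions for fragmented and empty
#' networks (the dominant case in an activity-stratified ensemble) are:
#' closeness sums geodesic distances over reachable vertices only and isolates
#' score 0; per-vertex clustering is 0 for degree < 2 and the average runs
#' over all N vertices; betweenness is the raw Freeman sum over unordered
#' pairs (no normalization); eigenvector centrality is 0 everywhere on an
#' empty network and 0 on components not attaining the leading eigenvalue.
NULL

# accept a proximity_network or a bare adjacency matrix
as_adj <- function(x) {
  if (inherits(x, "proximity_network")) return(x$adjacency)
  a <- as.matrix(x)
  stopifnot(nrow(a) == ncol(a))
  storage.mode(a) <- "integer"
  a
}

neighbor_list <- function(adj) {
  lapply(seq_len(nrow(adj)), function(i) which(adj[i, ] != 0L))
}

#' Network density
#'
#' The fraction of realized edges among all ordered vertex pairs:
#' `sum(adjacency) / (N^2 - N)` (each undirected edge counts twice in the
#' numerator, matching the denominator's ordered pairs).
#'
#' @param x a [proximity_network()] or adjacency matrix; N >= 2.
#' @return Density in \[0, 1\].
#' @export
net_density <- function(x) {
  adj <- as_adj(x)
  n <- nrow(adj)
  if (n < 2L) stop("density needs at least 2 vertices", call. = FALSE)
  sum(adj) / (n^2 - n)
}

#' Number of connected components
#'
#' Counted by graph traversal; isolated vertices are singleton components, so
#' an empty N-vertex network has N components.
#'
#' @inheritParams net_density
#' @return Integer component count in \[1, N\].
#' @export
count_components <- function(x) {
  adj <- as_adj(x)
  n <- nrow(adj)
  if (n == 0L) return(0L)
  nb <- neighbor_list(adj)
  seen <- logical(n)
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      new <- nb[[v]][!seen[nb[[v]]]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
  }
  ncomp
}

#' Clustering coefficient
#'
#' Average over vertices of the per-vertex coefficient `CC_i`: the fraction of
#' pairs of i's neighbors that are themselves connected. Vertices with degree
#' below 2 contribute `CC_i = 0`. By default the average runs over all N
#' vertices (the formula divides by N); `include_low_degree = FALSE` averages
#' over vertices of degree >= 2 only.
#'
#' @inheritParams net_density
#' @param include_low_degree include degree < 2 vertices (as zeros) in the
#'   average.
#' @return Scalar in \[0, 1\]; 0 for an empty network (also under
#'   `include_low_degree = FALSE`, where no vertex qualifies).
#' @export
clustering_coefficient <- function(x, include_low_degree = TRUE) {
  adj <- as_adj(x)
  n <- nrow(adj)
  deg <- rowSums(adj)
  cc <- numeric(n)
  for (i in which(deg >= 2)) {
    nbr <- which(adj[i, ] != 0L)
    links <- sum(adj[nbr, nbr]) / 2
    cc[i] <- links / (length(nbr) * (length(nbr) - 1) / 2)
  }
  if (include_low_degree) {
    mean(cc)
  } else {
    k <- sum(deg >= 2)
    if (k == 0L) 0 else sum(cc) / k
  }
}

#' Degree centrality
#'
#' Row sums of the adjacency matrix: the number of direct proximity partners.
#'
#' @inheritParams net_density
#' @return Named integer vector over the vertices.
#' @export
degree_centrality <- function(x) {
  adj <- as_adj(x)
  out <- as.integer(rowSums(adj))
  names(out) <- rownames(adj)
  out
}

# BFS distances from source s; unreachable = NA
bfs_distances <- function(nb, n, s) {
  d <- rep(NA_integer_, n)
  d[s] <- 0L
  queue <- s
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    new <- nb[[v]][is.na(d[nb[[v]]])]
    d[new] <- d[v] + 1L
    queue <- c(queue, new)
  }
  d
}

#' Closeness centrality
#'
#' Reciprocal of the sum of geodesic (shortest-path, unweighted) distances
#' from a vertex to every vertex reachable from it. On fragmented networks the
#' sum runs over the vertex's own component only; isolated vertices score 0.
#'
#' @inheritParams net_density
#' @return Named numeric vector over the vertices.
#' @export
closeness_centrality <- function(x) {
  adj <- as_adj(x)
  n <- nrow(adj)
  nb <- neighbor_list(adj)
  deg <- lengths(nb)
  out <- numeric(n)
  for (i in which(deg > 0L)) {
    d <- bfs_distances(nb, n, i)
    out[i] <- 1 / sum(d[-i], na.rm = TRUE)
  }
  names(out) <- rownames(adj)
  out
}

#' Betweenness centrality
#'
#' Freeman betweenness: for each vertex i, the sum over unordered pairs
#' {j, k} (j, k != i) of the fraction of geodesic paths between j and k that
#' pass through i. Endpoints are excluded, pairs in different components
#' contribute 0, and no normalization is applied. Computed with Brandes'
#' dependency-accumulation algorithm (halved to count unordered pairs once).
#'
#' @inheritParams net_density
#' @return Named numeric vector over the vertices.
#' @export
betweenness_centrality <- function(x) {
  adj <- as_adj(x)
  n <- nrow(adj)
  nb <- neighbor_list(adj)
  deg <- lengths(nb)
  bc <- numeric(n)
  for (s in which(deg > 0L)) {
    dist <- rep(-1L, n)
    sigma <- numeric(n)
    dist[s] <- 0L
    sigma[s] <- 1
    pred <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      order_visited <- c(order_visited, v)
      for (w in nb[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          pred[[w]] <- c(pred[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in pred[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2
  names(bc) <- rownames(adj)
  bc
}

#' Eigenvector centrality
#'
#' The Perron-Frobenius eigenvector of the adjacency matrix, normalized so the
#' maximum entry is 1. Computed by power iteration from the all-ones start
#' vector on the spectrally shifted matrix A + I (the shift leaves the
#' eigenvectors unchanged but makes the iteration converge on bipartite
#' components, e.g. stars, where the unshifted iteration oscillates).
#' Components whose leading eigenvalue falls short of the network's largest
#' decay to zero; entries below `zero_tol` after convergence are set to
#' exactly 0, so only the dominant component(s) score. An empty network (and
#' every isolated vertex) scores 0. When several components tie for the
#' leading eigenvalue, the symmetric all-ones start retains them all.
#'
#' @details
#' The iteration runs separately on each connected component (where the
#' Perron root is simple, so convergence is geometric); the per-component
#' leading eigenvalues are then compared and only components attaining the
#' network-wide maximum (ties within `1e-8`) keep their — max-1 normalized —
#' entries. Running on the whole matrix at once would mix components whose
#' leading eigenvalues differ by an arbitrarily small amount and stall the
#' iteration; the componentwise result is identical in exact arithmetic.
#'
#' @inheritParams net_density
#' @param tol convergence threshold on the max-norm change between successive
#'   normalized iterates.
#' @param max_iter iteration cap per component; exceeding it is an error
#'   reporting the residual.
#' @param zero_tol entries below this after convergence are clamped to 0;
#'   also the tie tolerance between component eigenvalues.
#' @return Named numeric vector over the vertices, max entry 1 (all zeros for
#'   an empty network); the leading eigenvalue is attached as attribute
#'   `"eigenvalue"`.
#' @export
eigenvector_centrality <- function(x, tol = 1e-10, max_iter = 10000L,
                                   zero_tol = 1e-8) {
  adj <- as_adj(x)
  n <- nrow(adj)
  deg <- rowSums(adj)
  out <- numeric(n)
  names(out) <- rownames(adj)
  active <- which(deg > 0)
  if (length(active) == 0L) {
    attr(out, "eigenvalue") <- 0
    return(out)
  }
  nb <- neighbor_list(adj)
  comp <- rep(0L, n)
  ncomp <- 0L
  for (s in active) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    queue <- s
    comp[s] <- ncomp
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      new <- nb[[v]][comp[nb[[v]]] == 0L]
      comp[new] <- ncomp
      queue <- c(queue, new)
    }
  }
  lambdas <- numeric(ncomp)
  vecs <- vector("list", ncomp)
  members <- vector("list", ncomp)
  for (cc in seq_len(ncomp)) {
    idx <- which(comp == cc)
    members[[cc]] <- idx
    m <- adj[idx, idx, drop = FALSE]
    storage.mode(m) <- "double"
    v <- rep(1, length(idx))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      v_new <- as.vector(m %*% v) + v  # (A + I) v: converges on bipartite too
      v_new <- v_new / max(v_new)
      if (max(abs(v_new - v)) < tol) {
        v <- v_new
        converged <- TRUE
        break
      }
      v <- v_new
    }
    av <- as.vector(m %*% v)
    lambda <- sum(v * av) / sum(v * v)
    if (!converged) {
      stop(sprintf(
        "power iteration did not converge in %d iterations (residual %.3e)",
        max_iter, max(abs(av - lambda * v))), call. = FALSE)
    }
    lambdas[cc] <- lambda
    vecs[[cc]] <- v
  }
  lam_max <- max(lambdas)
  for (cc in which(lambdas >= lam_max - zero_tol * max(1, lam_max))) {
    v <- vecs[[cc]]
    v[v < zero_tol] <- 0
    out[members[[cc]]] <- v
  }
  attr(out, "eigenvalue") <- lam_max
  out
}

# all indices of one network in one pass (shared neighbor lists)
indices_one <- function(net) {
  adj <- net$adjacency
  n <- nrow(adj)
  deg <- degree_centrality(net)
  list(
    density = if (n >= 2L) net_density(adj) else NA_real_,
    n_components = count_components(adj),
    clustering = clustering_coefficient(adj),
    degree = deg,
    closeness = closeness_centrality(adj),
    betweenness = betweenness_centrality(adj),
    eigenvector = as.vector(eigenvector_centrality(adj))
  )
}

#' Compute the index table of an ensemble
#'
#' One global-index row per network and one local-index row per
#' (network, vertex); for a complete design with P periods and N animals that
#' is `7 * P` global rows and `7 * P * N` local rows.
#'
#' @param ensemble a `network_ensemble` from [build_ensemble()].
#' @return A `herd_index_table`: list with data frames `global`
#'   (`network_id, activity, period, density, n_components, clustering`) and
#'   `local` (`network_id, activity, period, animal_id, degree, closeness,
#'   betweenness, eigenvector`).
#' @export
compute_index_table <- function(ensemble) {
  stopifnot(inherits(ensemble, "network_ensemble"))
  nets <- ensemble$networks
  k <- length(nets)
  n <- length(ensemble$vertex_ids)
  g_act <- character(k); g_per <- integer(k)
  g_den <- numeric(k); g_cmp <- integer(k); g_clu <- numeric(k)
  l_deg <- integer(k * n); l_clo <- numeric(k * n)
  l_bet <- numeric(k * n); l_eig <- numeric(k * n)
  for (idx in seq_len(k)) {
    net <- nets[[idx]]
    res <- indices_one(net)
    g_act[idx] <- net$activity
    g_per[idx] <- net$period_id
    g_den[idx] <- res$density
    g_cmp[idx] <- res$n_components
    g_clu[idx] <- res$clustering
    off <- (idx - 1L) * n
    l_deg[off + seq_len(n)] <- res$degree
    l_clo[off + seq_len(n)] <- res$closeness
    l_bet[off + seq_len(n)] <- res$betweenness
    l_eig[off + seq_len(n)] <- res$eigenvector
  }
  ids <- names(nets)
  global <- data.frame(network_id = ids, activity = g_act, period = g_per,
                       density = g_den, n_components = g_cmp,
                       clustering = g_clu, stringsAsFactors = FALSE)
  local <- data.frame(network_id = rep(ids, each = n),
                      activity = rep(g_act, each = n),
                      period = rep(g_per, each = n),
                      animal_id = rep(ensemble$vertex_ids, times = k),
                      degree = l_deg, closeness = l_clo,
                      betweenness = l_bet, eigenvector = l_eig,
                      stringsAsFactors = FALSE)
  structure(list(global = global, local = local),
            class = "herd_index_table")
}

#' Write an index table as two CSVs
#'
#' @param index_table a `herd_index_table`.
#' @param dir output directory (created if needed).
#' @return Paths of the two files, invisibly.
#' @export
write_index_table <- function(index_table, dir) {
  stopifnot(inherits(index_table, "herd_index_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gp <- file.path(dir, "indices_global.csv")
  lp <- file.path(dir, "indices_local.csv")
  utils::write.csv(index_table$global, gp, row.names = FALSE, quote = FALSE)
  utils::write.csv(index_table$local, lp, row.names = FALSE, quote = FALSE)
  invisible(c(global = gp, local = lp))
}
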