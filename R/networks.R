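#' Construct a proximity network
#'
#' A proximity network is a binary, symmetric, zero-diagonal adjacency matrix
#' over the full-herd vertex set for one (activity, period) pair. Animals not
#' performing the activity in that period are isolated vertices; every network
#' of a run carries the same vertices in the same (roster) order.
#'
#' @param activity one of [activities()].
#' @param period_id integer period reference.
#' @param vertex_ids character vector of animal IDs (roster order).
#' @param adjacency N x N binary matrix; symmetric with zero diagonal.
#' @return A `proximity_network` object.
#' @export
proximity_network <- function(activity, period_id, vertex_ids, adjacency) {
  check_activity(activity)
  adjacency <- as.matrix(adjacency)
  n <- length(vertex_ids)
  stopifnot(nrow(adjacency) == n, ncol(adjacency) == n)
  storage.mode(adjacency) <- "integer"
  if (!all(adjacency %in% c(0L, 1L))) {
    stop("adjacency must be binary", call. = FALSE)
  }
  if (!identical(adjacency, t(adjacency))) {
    stop("adjacency must be symmetric (proximity is reciprocal)",
         call. = FALSE)
  }
  if (any(diag(adjacency) != 0L)) {
    stop("adjacency diagonal must be zero (no self-proximity)", call. = FALSE)
  }
  dimnames(adjacency) <- list(vertex_ids, vertex_ids)
  structure(list(activity = activity,
                 period_id = as.integer(period_id),
                 vertex_ids = as.character(vertex_ids),
                 adjacency = adjacency),
            class = "proximity_network")
}

network_id <- function(activity, period_id) {
  sprintf("%s_p%03d", activity, period_id)
}

#' Build the activity-stratified network ensemble
#'
#' One binary undirected network per (activity, period) over the fixed
#' full-herd vertex set: the edge (i, j) is present exactly when j is a
#' recorded proximity partner of i in that period and both animals perform
#' that activity. Every combination is present — activities that did not occur
#' in a period yield empty (all-zero) networks — so a complete design gives
#' `7 * n_periods` networks.
#'
#' @param records a `herd_records` data frame (validated; see
#'   [validate_records()]).
#' @param roster a `herd_roster`; defines the vertex set and its order.
#' @return A `network_ensemble`: list with `networks` (named list of
#'   [proximity_network()]s), `vertex_ids`, `periods`, `n_periods`.
#' @export
build_ensemble <- function(records, roster) {
  roster <- validate_roster(roster)
  if (!inherits(records, "herd_records")) {
    records <- validate_records(records, roster)
  }
  if (!all(records$animal_id %in% roster$animal_id)) {
    stop("records reference animals outside the roster", call. = FALSE)
  }
  ids <- roster$animal_id
  n <- length(ids)
  idx_of <- stats::setNames(seq_len(n), ids)
  periods <- sort(unique(records$period_id))
  plist <- split_partners(records$partners)

  nets <- vector("list", 7L * length(periods))
  names(nets) <- as.vector(outer(activities(), periods, network_id))
  rec_by_period <- split(seq_len(nrow(records)), records$period_id)

  for (p in periods) {
    rows <- rec_by_period[[as.character(p)]]
    act_of_row <- records$activity[rows]
    for (a in activities()) {
      adj <- matrix(0L, n, n)
      sel <- rows[act_of_row == a]
      for (r in sel) {
        pr <- plist[[r]]
        if (length(pr) > 0L) {
          i <- idx_of[[records$animal_id[r]]]
          j <- idx_of[pr]
          adj[cbind(i, j)] <- 1L
          adj[cbind(j, i)] <- 1L
        }
      }
      nets[[network_id(a, p)]] <- proximity_network(a, p, ids, adj)
    }
  }
  structure(list(networks = nets,
                 vertex_ids = ids,
                 periods = periods,
                 n_periods = length(periods)),
            class = "network_ensemble")
}

#' @export
print.network_ensemble <- function(x, ...) {
  cat(sprintf("network_ensemble: %d networks (%d activities x %d periods), %d vertices each\n",
              length(x$networks), length(activities()), x$n_periods,
              length(x$vertex_ids)))
  invisible(x)
}

#' Write a proximity network to file
#'
#' `"edgelist"` writes a CSV of edges (`from,to`, one row per unordered edge)
#' plus a `<path>.vertices.csv` sidecar declaring all vertices so isolates
#' survive the round trip. `"graphml"` writes GraphML with all vertices
#' declared and `activity`/`period_id` as graph attributes.
#'
#' @param network a [proximity_network()].
#' @param path output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  adj <- network$adjacency
  if (format == "edgelist") {
    idx <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
    edges <- data.frame(from = network$vertex_ids[idx[, 1L]],
                        to = network$vertex_ids[idx[, 2L]],
                        stringsAsFactors = FALSE)
    utils::write.csv(edges[order(edges$from, edges$to), , drop = FALSE],
                     path, row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(animal_id = network$vertex_ids),
                     paste0(path, ".vertices.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    g <- igraph::set_graph_attr(g, "activity", network$activity)
    g <- igraph::set_graph_attr(g, "period_id", network$period_id)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a proximity network written by [write_network()]
#'
#' @param path path written by [write_network()].
#' @param format `"edgelist"` or `"graphml"`.
#' @param activity,period_id metadata for the edgelist format (not stored in
#'   the CSV itself); ignored for GraphML, which carries them as attributes.
#' @return A [proximity_network()].
#' @export
read_network <- function(path, format = c("edgelist", "graphml"),
                         activity = NULL, period_id = NA_integer_) {
  format <- match.arg(format)
  if (format == "edgelist") {
    edges <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    verts <- utils::read.csv(paste0(path, ".vertices.csv"),
                             stringsAsFactors = FALSE,
                             colClasses = "character")$animal_id
    n <- length(verts)
    adj <- matrix(0L, n, n)
    if (nrow(edges) > 0L) {
      i <- match(edges$from, verts)
      j <- match(edges$to, verts)
      if (anyNA(i) || anyNA(j)) {
        stop("edge references a vertex missing from the vertex sidecar",
             call. = FALSE)
      }
      adj[cbind(i, j)] <- 1L
      adj[cbind(j, i)] <- 1L
    }
    if (is.null(activity)) activity <- "grazing"
    proximity_network(activity, period_id, verts, adj)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    proximity_network(igraph::graph_attr(g, "activity"),
                      igraph::graph_attr(g, "period_id"),
                      igraph::V(g)$name %||% as.character(seq_len(nrow(adj))),
                      adj)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
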