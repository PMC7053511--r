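#' Spearman rank correlation with tie handling
#'
#' rho is the Pearson correlation of midranks (average ranks for ties). The
#' two-tailed p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom;
#' `rho = +/-1` returns `p = 0`. For small samples an exact permutation
#' p-value (full enumeration) is available for `n <= 8`.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, each with at least two
#'   distinct values (a constant vector is an error: the correlation is
#'   undefined).
#' @param exact use the permutation null instead of the t approximation
#'   (`n <= 8` only).
#' @return List with `rho`, `p`, `n`, `significance` (`"ns"`, `"p<0.05"`,
#'   `"p<0.01"`).
#' @export
#' @examples
#' spearman_test(c(1, 1, 0, 0), c(4, 3, 2, 1))$rho  # 4 / sqrt(20)
spearman_test <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("constant vector: Spearman correlation undefined", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8L) stop("exact permutation p only supported for n <= 8",
                     call. = FALSE)
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, function(ix) stats::cor(rx, ry[ix]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, significance = significance_label(p))
}

significance_label <- function(p) {
  if (is.na(p)) NA_character_
  else if (p < 0.01) "p<0.01"
  else if (p < 0.05) "p<0.05"
  else "ns"
}

# all permutations of 1..n as a matrix (n! rows); n is small by construction
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (i in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(k, rest[sub[i, ]])
    }
  }
  out
}

GLOBAL_INDICES <- c("density", "n_components", "clustering")
LOCAL_INDICES <- c("degree", "closeness", "betweenness", "eigenvector")

#' Assemble the three analysis data sets
#'
#' \enumerate{
#'   \item `global_vs_activity`: one row per network — the three global
#'     indices plus seven binary activity indicators (exactly one is 1 per
#'     row, the network's own activity).
#'   \item `local_vs_activity`: one row per (network, vertex) — the four
#'     centralities plus the same indicators.
#'   \item `attribute_vs_centrality`: one row per (network, vertex) — the
#'     centralities plus the vertex's `age` and `gender` (1 = female,
#'     2 = male) and the network's activity, analysed one activity at a time.
#' }
#'
#' @param index_table a `herd_index_table` from [compute_index_table()].
#' @param roster a `herd_roster`.
#' @return A `herd_datasets` list with the three data frames.
#' @export
assemble_datasets <- function(index_table, roster) {
  stopifnot(inherits(index_table, "herd_index_table"))
  roster <- validate_roster(roster)
  add_indicators <- function(df) {
    for (a in activities()) df[[a]] <- as.integer(df$activity == a)
    df
  }
  ds1 <- add_indicators(index_table$global)
  ds2 <- add_indicators(index_table$local)
  ds3 <- index_table$local
  m <- match(ds3$animal_id, roster$animal_id)
  if (anyNA(m)) stop("index table references animals outside the roster",
                     call. = FALSE)
  ds3$age <- roster$age[m]
  ds3$gender <- roster$gender[m]
  structure(list(global_vs_activity = ds1,
                 local_vs_activity = ds2,
                 attribute_vs_centrality = ds3),
            class = "herd_datasets")
}

one_association <- function(x, y, variable, index, context = NA_character_) {
  res <- tryCatch(spearman_test(x, y), error = function(e) e)
  if (inherits(res, "error")) {
    data.frame(variable = variable, index = index,
               activity_context = context, n = sum(is.finite(x * y)),
               rho = NA_real_, p = NA_real_, significance = NA_character_,
               note = conditionMessage(res), stringsAsFactors = FALSE)
  } else {
    data.frame(variable = variable, index = index,
               activity_context = context, n = res$n, rho = res$rho,
               p = res$p, significance = res$significance, note = "",
               stringsAsFactors = FALSE)
  }
}

#' Run all Spearman associations
#'
#' Data set 1: each activity indicator against each global index (7 x 3).
#' Data set 2: each indicator against each centrality (7 x 4). Data set 3:
#' within each activity's networks, age and gender against each centrality
#' (7 x 2 x 4). Pairs with a constant vector (e.g. an activity that never
#' occurred) are reported with `rho = NA` and the reason in `note`.
#'
#' @param datasets a `herd_datasets` from [assemble_datasets()].
#' @return A `herd_associations` list of three result data frames
#'   (`global`, `local`, `attribute`), each with columns `variable`, `index`,
#'   `activity_context`, `n`, `rho`, `p`, `significance`, `note`.
#' @export
run_associations <- function(datasets) {
  stopifnot(inherits(datasets, "herd_datasets"))
  ds1 <- datasets$global_vs_activity
  ds2 <- datasets$local_vs_activity
  ds3 <- datasets$attribute_vs_centrality

  global <- do.call(rbind, lapply(activities(), function(a) {
    do.call(rbind, lapply(GLOBAL_INDICES, function(ix) {
      one_association(ds1[[a]], ds1[[ix]], a, ix)
    }))
  }))
  local <- do.call(rbind, lapply(activities(), function(a) {
    do.call(rbind, lapply(LOCAL_INDICES, function(ix) {
      one_association(ds2[[a]], ds2[[ix]], a, ix)
    }))
  }))
  attribute <- do.call(rbind, lapply(activities(), function(a) {
    sub <- ds3[ds3$activity == a, , drop = FALSE]
    do.call(rbind, lapply(c("age", "gender"), function(v) {
      do.call(rbind, lapply(LOCAL_INDICES, function(ix) {
        one_association(sub[[v]], sub[[ix]], v, ix, context = a)
      }))
    }))
  }))
  structure(list(global = global, local = local, attribute = attribute),
            class = "herd_associations")
}

format_cell <- function(rho, p) {
  if (is.na(rho)) return("NA")
  stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  sprintf("%.2f%s", rho, stars)
}

#' Correlogram tables
#'
#' Matrix-form summaries of the association results: signed rho with
#' significance markers (`*` for p < 0.05, `**` for p < 0.01), one table per
#' data set. For the attribute data set rows are (activity, variable) pairs.
#'
#' @param associations a `herd_associations` from [run_associations()].
#' @return Named list of three data frames of formatted cells.
#' @export
correlogram_table <- function(associations) {
  stopifnot(inherits(associations, "herd_associations"))
  wide <- function(df, row_keys, col_key) {
    rows <- unique(df[, row_keys, drop = FALSE])
    cols <- unique(df[[col_key]])
    out <- as.data.frame(rows, stringsAsFactors = FALSE)
    for (cl in cols) out[[cl]] <- NA_character_
    for (i in seq_len(nrow(df))) {
      r <- which(apply(rows, 1L, function(rk) {
        all(rk == unlist(df[i, row_keys]))
      }))
      out[r, df$index[i]] <- format_cell(df$rho[i], df$p[i])
    }
    rownames(out) <- NULL
    out
  }
  list(global = wide(associations$global, "variable", "index"),
       local = wide(associations$local, "variable", "index"),
       attribute = wide(associations$attribute,
                        c("activity_context", "variable"), "index"))
}

#' Write association results and correlograms
#'
#' Results as one CSV per data set, correlograms as CSV plus fixed-width text.
#'
#' @param associations a `herd_associations`.
#' @param dir output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
write_associations <- function(associations, dir) {
  stopifnot(inherits(associations, "herd_associations"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(associations)) {
    utils::write.csv(associations[[nm]],
                     file.path(dir, sprintf("associations_%s.csv", nm)),
                     row.names = FALSE)
  }
  tables <- correlogram_table(associations)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]],
                     file.path(dir, sprintf("correlogram_%s.csv", nm)),
                     row.names = FALSE)
    txt <- utils::capture.output(print(tables[[nm]], right = TRUE))
    writeLines(txt, file.path(dir, sprintf("correlogram_%s.txt", nm)))
  }
  invisible(dir)
}
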