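#' Run the full proximity-network analysis
#'
#' Orchestrates the whole pipeline: (simulate or accept) roster and records,
#' build the activity-stratified network ensemble, compute the index table,
#' assemble the three analysis data sets, and run all Spearman associations.
#' With `output_dir` set, writes roster, records, index tables, association
#' results and correlograms there. Fully deterministic: all randomness lives
#' in the generator seed; the analysis stages have none.
#'
#' @param config a [generator_config()]; used only when `roster`/`records`
#'   are not supplied.
#' @param roster optional `herd_roster` (else simulated from `config`).
#' @param records optional `herd_records` (else simulated from `config`).
#' @param output_dir optional directory for CSV outputs.
#' @param verbose log progress and the headline counts via `message()`.
#' @return A `herd_analysis` list: `roster`, `records`, `ensemble`,
#'   `index_table`, `datasets`, `associations`, `correlograms`, and `counts`
#'   (`n_periods`, `n_networks`, `n_local_cases`, result counts).
#' @export
run_pipeline <- function(config = generator_config(), roster = NULL,
                         records = NULL, output_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(roster)) {
    roster <- generate_roster(config)
    say("simulated roster: %d animals", nrow(roster))
  }
  if (is.null(records)) {
    records <- generate_records(config, roster)
    say("simulated records: %d rows over %d periods", nrow(records),
        length(unique(records$period_id)))
  }
  ensemble <- build_ensemble(records, roster)
  say("built %d proximity networks (%d activities x %d periods)",
      length(ensemble$networks), length(activities()), ensemble$n_periods)
  index_table <- compute_index_table(ensemble)
  say("computed indices: %d networks, %d local cases",
      nrow(index_table$global), nrow(index_table$local))
  datasets <- assemble_datasets(index_table, roster)
  associations <- run_associations(datasets)
  n_res <- vapply(associations, nrow, integer(1))
  say("associations: %d global, %d local, %d attribute results",
      n_res[["global"]], n_res[["local"]], n_res[["attribute"]])
  correlograms <- correlogram_table(associations)
  counts <- list(n_animals = nrow(roster),
                 n_periods = ensemble$n_periods,
                 n_networks = length(ensemble$networks),
                 n_local_cases = nrow(index_table$local),
                 n_global_results = n_res[["global"]],
                 n_local_results = n_res[["local"]],
                 n_attribute_results = n_res[["attribute"]])
  out <- structure(list(roster = roster, records = records,
                        ensemble = ensemble, index_table = index_table,
                        datasets = datasets, associations = associations,
                        correlograms = correlograms, counts = counts),
                   class = "herd_analysis")
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    write_roster(roster, file.path(output_dir, "roster.csv"))
    write_records(records, file.path(output_dir, "records.csv"))
    write_index_table(index_table, output_dir)
    write_associations(associations, output_dir)
    say("wrote outputs to %s", output_dir)
  }
  out
}

#' @export
print.herd_analysis <- function(x, ...) {
  c0 <- x$counts
  cat(sprintf(
    "herd_analysis: %d animals, %d periods -> %d networks, %d local cases\n",
    c0$n_animals, c0$n_periods, c0$n_networks, c0$n_local_cases))
  cat(sprintf("associations: %d global, %d local, %d attribute\n",
              c0$n_global_results, c0$n_local_results,
              c0$n_attribute_results))
  invisible(x)
}

#' Look up one association result
#'
#' Convenience accessor: the Spearman rho/p for one (variable, index) pair
#' from a `herd_analysis`, e.g. grazing vs density, or age vs degree within
#' lying networks.
#'
#' @param analysis a `herd_analysis` from [run_pipeline()].
#' @param variable an activity name (data sets 1-2) or `"age"`/`"gender"`
#'   (data set 3).
#' @param index an index name (`density`, `n_components`, `clustering`,
#'   `degree`, `closeness`, `betweenness`, `eigenvector`).
#' @param activity_context activity restriction, required for age/gender.
#' @return One-row data frame with `rho`, `p`, `n`, `significance`.
#' @export
association_of <- function(analysis, variable, index,
                           activity_context = NULL) {
  stopifnot(inherits(analysis, "herd_analysis"))
  if (variable %in% c("age", "gender")) {
    df <- analysis$associations$attribute
    df <- df[df$variable == variable & df$index == index &
               df$activity_context == activity_context, , drop = FALSE]
  } else {
    df <- if (index %in% GLOBAL_INDICES) analysis$associations$global
          else analysis$associations$local
    df <- df[df$variable == variable & df$index == index, , drop = FALSE]
  }
  if (nrow(df) != 1L) stop("no such association", call. = FALSE)
  df[, c("variable", "index", "activity_context", "n", "rho", "p",
         "significance")]
}
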