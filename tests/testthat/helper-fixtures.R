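# tiny in-code fixtures for the records / network tests

toy_roster <- function(ids = c("A", "B", "C", "D"),
                       age = seq_along(ids) + 1,
                       gender = rep(1L, length(ids))) {
  herd_roster(ids, age, gender)
}

# build a records data frame from (period, animal, activity, partners) rows
rec_df <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(period_id = r[[1]],
               animal_id = r[[2]], activity = r[[3]],
               partners = r[[4]], stringsAsFactors = FALSE)
  }))
  df$month <- (df$period_id - 1L) %/% 20L + 1L
  df$session <- ((df$period_id - 1L) %% 20L) %/% 10L + 1L
  df$time_step <- (df$period_id - 1L) %% 10L + 1L
  df
}

small_config <- function(seed = 11, n_periods = 6, ...) {
  generator_config(seed = seed, n_periods = n_periods, ...)
}
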