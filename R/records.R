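#' @name herd_records
#' @title Focal-sampling observation records
#'
#' @description
#' Observation records hold one row per (animal, period): the single activity
#' the animal performed in that 30-minute period and the set of proximity
#' partners recorded for it (animals within the proximity criterion performing
#' the same activity). Partners are stored as a semicolon-joined string in the
#' `partners` column; the empty string means no partners.
#'
#' Validation enforces the observation-design invariants:
#' \itemize{
#'   \item exactly one record per (animal, period) — activities are mutually
#'     exclusive within a period;
#'   \item an animal is never its own partner;
#'   \item every partner is a roster animal observed in the same period
#'     performing the same activity;
#'   \item proximity is reciprocal: partner sets are symmetrized by union, with
#'     a warning when the raw data listed only one side of a pair.
#' }
NULL

split_partners <- function(x) {
  if (length(x) == 0L) return(list())
  strsplit(ifelse(is.na(x) | x == "", "", as.character(x)), ";", fixed = TRUE)
}

join_partners <- function(lst) {
  vapply(lst, function(p) paste(sort(unique(p)), collapse = ";"), character(1))
}

#' Validate (and symmetrize) observation records
#'
#' @param records data frame with columns `period_id`, `month`, `session`,
#'   `time_step`, `animal_id`, `activity`, `partners`.
#' @param roster a `herd_roster`; all animals and partners must appear in it.
#' @return A `herd_records` data frame with canonical (sorted, symmetric)
#'   partner strings.
#' @export
validate_records <- function(records, roster) {
  roster <- validate_roster(roster)
  req <- c("period_id", "month", "session", "time_step",
           "animal_id", "activity", "partners")
  missing <- setdiff(req, names(records))
  if (length(missing) > 0L) {
    stop(sprintf("records are missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  records <- as.data.frame(records)[, req]
  records$animal_id <- as.character(records$animal_id)
  records$activity <- as.character(records$activity)
  records$partners <- ifelse(is.na(records$partners), "",
                             as.character(records$partners))
  for (col in c("period_id", "month", "session", "time_step")) {
    records[[col]] <- as.integer(records[[col]])
  }

  unknown <- which(!(records$animal_id %in% roster$animal_id))
  if (length(unknown) > 0L) {
    stop(sprintf("row %d: unknown animal_id '%s'",
                 unknown[1], records$animal_id[unknown[1]]), call. = FALSE)
  }
  bad_act <- which(!(records$activity %in% activities()))
  if (length(bad_act) > 0L) {
    stop(sprintf("row %d: unknown activity '%s'",
                 bad_act[1], records$activity[bad_act[1]]), call. = FALSE)
  }

  key <- paste(records$period_id, records$animal_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop(sprintf(
      "row %d: second record for animal '%s' in period %d (activities are mutually exclusive: one observation per animal per period)",
      dup[1], records$animal_id[dup[1]], records$period_id[dup[1]]),
      call. = FALSE)
  }
  # period_id must map to a single (month, session, time_step)
  ptab <- unique(records[, c("period_id", "month", "session", "time_step")])
  if (anyDuplicated(ptab$period_id)) {
    stop("period_id is not a bijection onto (month, session, time_step)",
         call. = FALSE)
  }

  plist <- split_partners(records$partners)
  row_of <- stats::setNames(seq_len(nrow(records)), key)
  n_pairs <- lengths(plist)
  asym <- 0L
  add <- vector("list", nrow(records))
  for (i in which(n_pairs > 0L)) {
    for (p in plist[[i]]) {
      if (p == records$animal_id[i]) {
        stop(sprintf("row %d: animal '%s' listed as its own partner",
                     i, p), call. = FALSE)
      }
      if (!(p %in% roster$animal_id)) {
        stop(sprintf("row %d: unknown partner '%s'", i, p), call. = FALSE)
      }
      j <- row_of[paste(records$period_id[i], p, sep = "\r")]
      if (is.na(j)) {
        stop(sprintf(
          "row %d: partner '%s' has no observation in period %d",
          i, p, records$period_id[i]), call. = FALSE)
      }
      if (records$activity[j] != records$activity[i]) {
        stop(sprintf(
          "row %d: partner '%s' performs '%s' while focal animal performs '%s' (proximity requires the same activity)",
          i, p, records$activity[j], records$activity[i]), call. = FALSE)
      }
      if (!(records$animal_id[i] %in% plist[[j]])) {
        asym <- asym + 1L
        add[[j]] <- c(add[[j]], records$animal_id[i])
      }
    }
  }
  if (asym > 0L) {
    warning(sprintf(
      "symmetrized %d one-sided proximity pair(s) by union (proximity is reciprocal)",
      asym), call. = FALSE)
    for (j in which(lengths(add) > 0L)) {
      plist[[j]] <- c(plist[[j]], add[[j]])
    }
  }
  records$partners <- join_partners(plist)
  records <- records[order(records$period_id,
                           match(records$animal_id, roster$animal_id)), ]
  rownames(records) <- NULL
  class(records) <- c("herd_records", "data.frame")
  records
}

#' Read observation records from CSV
#'
#' Columns: `period_id`, `month`, `session`, `time_step`, `animal_id`,
#' `activity`, `partners` (semicolon-joined IDs; empty = none). Records are
#' validated against the roster and partner sets are symmetrized
#' (see [validate_records()]).
#'
#' @param path path to a CSV file.
#' @param roster a `herd_roster`.
#' @return A `herd_records` data frame.
#' @export
read_records <- function(path, roster) {
  if (!file.exists(path)) stop(sprintf("records file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(animal_id = "character",
                                       partners = "character"))
  validate_records(df, roster)
}

#' Write observation records to CSV
#'
#' Round-trip safe: `read_records(write_records(x, p), roster)` reproduces `x`
#' exactly. An empty record set writes a header-only file.
#'
#' @param records a `herd_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  cols <- c("period_id", "month", "session", "time_step",
            "animal_id", "activity", "partners")
  utils::write.csv(as.data.frame(records)[, cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
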