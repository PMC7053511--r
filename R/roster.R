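#' Construct and validate a herd roster
#'
#' A roster is a data frame with one row per animal: `animal_id` (unique
#' character label), `age` (years, positive), and `gender` (1 = female,
#' 2 = male). String genders are recoded on input.
#'
#' @param animal_id character vector of unique labels.
#' @param age positive numeric vector (years).
#' @param gender codes 1/2 or strings "female"/"male".
#' @return A `herd_roster` data frame.
#' @export
#' @examples
#' herd_roster(c("B01", "B02"), c(9, 3), c("female", "male"))
herd_roster <- function(animal_id, age, gender) {
  roster <- data.frame(animal_id = as.character(animal_id),
                       age = as.numeric(age),
                       gender = gender_code(gender),
                       stringsAsFactors = FALSE)
  validate_roster(roster)
}

validate_roster <- function(roster) {
  stopifnot(is.data.frame(roster),
            all(c("animal_id", "age", "gender") %in% names(roster)))
  dup <- unique(roster$animal_id[duplicated(roster$animal_id)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate animal_id in roster: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  bad_age <- roster$animal_id[!is.finite(roster$age) | roster$age <= 0]
  if (length(bad_age) > 0L) {
    stop(sprintf("non-positive age for animal(s): %s",
                 paste(bad_age, collapse = ", ")), call. = FALSE)
  }
  roster$gender <- gender_code(roster$gender)
  class(roster) <- c("herd_roster", "data.frame")
  roster
}

#' Read a roster CSV
#'
#' Expects a header with columns `animal_id`, `age`, `gender` (genders as 1/2
#' or "female"/"male"). Duplicate IDs and non-positive ages are rejected with
#' an error naming the offending animal.
#'
#' @param path path to a CSV file.
#' @return A validated `herd_roster`.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) stop(sprintf("roster file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(animal_id = "character"))
  missing <- setdiff(c("animal_id", "age", "gender"), names(df))
  if (length(missing) > 0L) {
    stop(sprintf("roster is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  herd_roster(df$animal_id, df$age, df$gender)
}

#' Write a roster CSV
#'
#' @param roster a `herd_roster`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  roster <- validate_roster(roster)
  utils::write.csv(roster[, c("animal_id", "age", "gender")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
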