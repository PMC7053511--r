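#' The seven pasture activities
#'
#' The closed set of mutually exclusive activities an animal can perform in
#' one observation period: grazing, moving, standing, ruminating, wallowing,
#' lying, drinking. All activity columns in this package are validated against
#' this set; no other values are accepted.
#'
#' @return Character vector of length 7, in canonical order.
#' @export
#' @examples
#' activities()
activities <- function() {
  c("grazing", "moving", "standing", "ruminating",
    "wallowing", "lying", "drinking")
}

# Stop unless all values are valid activity names; `where` labels the error.
check_activity <- function(x, where = "activity") {
  bad <- setdiff(unique(as.character(x)), activities())
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s: %s (must be one of %s)",
                 where, paste(bad, collapse = ", "),
                 paste(activities(), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Gender codes
#'
#' Genders are coded numerically throughout: female = 1, male = 2. The string
#' forms "female"/"male" (any case) are accepted on input and recoded.
#'
#' @param x vector of codes (1/2) or strings ("female"/"male").
#' @return Integer vector of codes in {1, 2}.
#' @export
gender_code <- function(x) {
  if (is.numeric(x)) {
    out <- as.integer(x)
  } else {
    s <- tolower(trimws(as.character(x)))
    out <- ifelse(s %in% c("1", "female", "f"), 1L,
                  ifelse(s %in% c("2", "male", "m"), 2L, NA_integer_))
  }
  if (any(is.na(out) | !(out %in% c(1L, 2L)))) {
    bad <- unique(x[is.na(out) | !(out %in% c(1L, 2L))])
    stop(sprintf("invalid gender value(s): %s (use 1/2 or female/male)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}
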