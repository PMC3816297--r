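#' Normalize a timestamp to canonical ISO-8601 text
#'
#' Timestamps throughout the package are timezone-naive ISO-8601 strings
#' normalized to `YYYY-MM-DDTHH:MM:SS`. A date without a time-of-day is
#' anchored at midnight. On the normalized form, lexicographic order equals
#' chronological order, so all temporal restriction checks reduce to plain
#' string comparison.
#'
#' @param x Character, `Date` or `POSIXt` vector (or `NULL`). Accepted text
#'   forms: `"2012-03-01"`, `"2012-03-01 08:00"`, `"2012-03-01T08:00:00"`.
#' @return Character vector of normalized timestamps; `NA` maps to `NA`.
#' @examples
#' normalize_timestamp("2012-03-01 08:00")
#' normalize_timestamp(as.Date("2012-03-01"))
#' @export
normalize_timestamp <- function(x) {
  if (is.null(x) || length(x) == 0) return(NA_character_)
  if (inherits(x, "Date")) x <- format(x, "%Y-%m-%d")
  if (inherits(x, "POSIXt")) x <- format(x, "%Y-%m-%dT%H:%M:%S")
  x <- as.character(x)
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    s <- sub(" ", "T", trimws(s))
    if (!grepl("^\\d{4}-\\d{2}-\\d{2}(T\\d{2}:\\d{2}(:\\d{2})?)?$", s)) {
      abort(sprintf("not an ISO-8601 timestamp: '%s'", s),
            class = "provflow_bad_timestamp")
    }
    if (!grepl("T", s)) s <- paste0(s, "T00:00:00")
    if (grepl("T\\d{2}:\\d{2}$", s)) s <- paste0(s, ":00")
    s
  }, character(1), USE.NAMES = FALSE)
}

# strict / non-strict comparisons on normalized timestamps; NA-safe (NA
# participates in no violation: the paper's vacuous-satisfaction reading)
ts_lt <- function(a, b) !is.na(a) & !is.na(b) & a < b
ts_le <- function(a, b) !is.na(a) & !is.na(b) & a <= b
ts_ge <- function(a, b) !is.na(a) & !is.na(b) & a >= b
ts_gt <- function(a, b) !is.na(a) & !is.na(b) & a > b
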