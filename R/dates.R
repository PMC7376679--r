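#' Parse a date in the three accepted dialects
#'
#' Event files carry dates as ISO 8601 (\code{YYYY-MM-DD}), day-first
#' (\code{DD/MM/YYYY}) or as a bare year (\code{YYYY}). The slash form is
#' always read day-first, never month-first; anything else is rejected rather
#' than guessed. A bare year is normalised to July 1 of that year so that
#' year-only events order sensibly among dated ones, while the original
#' precision is retained for display.
#'
#' @param text a single non-empty character string.
#' @return a list with elements \code{date} (a \code{Date}), \code{precision}
#'   (\code{"day"} or \code{"year"}) and \code{text} (the input, unchanged).
#' @examples
#' parse_date("2016-08-01")$date
#' parse_date("01/08/2016")$date   # day-first: 1 August 2016
#' parse_date("2016")$precision
#' @export
parse_date <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    st_date("empty date")
  txt <- trimws(text)
  if (grepl("^\\d{4}$", txt)) {
    y <- as.integer(txt)
    return(list(date = as.Date(sprintf("%04d-07-01", y)),
                precision = "year", text = txt))
  }
  iso <- NULL
  if (grepl("^\\d{4}-\\d{1,2}-\\d{1,2}$", txt)) {
    iso <- txt
  } else if (grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", txt)) {
    p <- as.integer(strsplit(txt, "/", fixed = TRUE)[[1]])
    iso <- sprintf("%04d-%02d-%02d", p[3], p[2], p[1])
  } else {
    st_date(sprintf("unparseable date '%s' (accepted: YYYY-MM-DD, DD/MM/YYYY, YYYY)", txt))
  }
  d <- as.Date(iso, format = "%Y-%m-%d")
  # as.Date() rolls over some invalid dates on certain platforms; round-trip
  # the components to reject e.g. 2016-13-01 or 31/02/2016.
  if (is.na(d) || format(d, "%Y-%m-%d") != sprintf("%04d-%02d-%02d",
      as.integer(substr(iso, 1, 4)), as.integer(substr(iso, 6, 7)),
      as.integer(substr(iso, 9, 10))))
    st_date(sprintf("invalid calendar date '%s'", txt))
  list(date = d, precision = "day", text = txt)
}

# Format a stored date for display: year-only dates show as the bare year.
st_format_date <- function(date, precision) {
  ifelse(precision == "year", format(date, "%Y"), format(date, "%Y-%m-%d"))
}
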