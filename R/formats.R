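# The six tabulated file formats. Header names are fixed here (and only
# here); a site using a different dialect remaps them via the header_map of
# app_config()/import_file().

st_format_table <- list(
  reproduction = c("event_id", "sown_seed_lot", "sowing_date", "location",
                   "actor", "quantity_sown_g", "harvest_date",
                   "quantity_harvested_g"),
  cross = c("event_id", "mother_seed_lot", "father_seed_lot", "date",
            "location", "actor"),
  selection = c("event_id", "parent_seed_lot", "selection_label", "date",
                "location", "actor", "quantity_used_g"),
  mixture = c("event_id", "parent_seed_lot", "quantity_used_g", "date",
              "location", "actor"),
  diffusion = c("event_id", "parent_seed_lot", "recipient_location",
                "recipient_person", "quantity_g", "date"),
  individual_measures = c("subject_seed_lot", "individual_index", "date")
)

#' The six tabulated file formats
#'
#' One format per event kind plus a sixth for individual measures. Every
#' format is tab-separated UTF-8 with a mandatory header row; any column
#' beyond the mandatory ones is a variable column holding measured data (see
#' Details). An empty cell always means missing, never zero.
#'
#' @details Variable-column headers follow the micro-syntax
#' \code{name[:method][@@date]}, optionally with a \code{#harvest} marker after
#' the name: \code{"awn_color"}, \code{"protein:NIRS@@2016-09-01"},
#' \code{"tkw#harvest"}. The method and date, when present, apply to every
#' value in the column (a column date overrides the row's event date). In
#' event files the value attaches to the relation, or to the harvested/child
#' lot when \code{#harvest} is given; in the individual-measures format it
#' attaches to the subject lot at individual level.
#'
#' @param kind optional single format name.
#' @return the list of all six format specs, or one spec: list(kind,
#'   mandatory_headers, allows_variable_columns).
#' @export
format_specs <- function(kind = NULL) {
  specs <- lapply(names(st_format_table), function(k)
    list(kind = k, mandatory_headers = st_format_table[[k]],
         allows_variable_columns = TRUE))
  names(specs) <- names(st_format_table)
  if (is.null(kind)) return(specs)
  if (!kind %in% names(specs))
    st_format(sprintf("unknown file format '%s' (expected one of: %s)", kind,
                      paste(names(specs), collapse = ", ")))
  specs[[kind]]
}

# Parse a variable-column header. Returns list(name, harvest, method, date)
# or NULL when the header is empty.
st_parse_var_header <- function(h) {
  h <- trimws(h)
  if (!nzchar(h)) return(NULL)
  m <- regmatches(h, regexec("^([^:@#]+?)\\s*(#harvest)?\\s*(?::([^@]*))?(?:@(.*))?$", h))[[1]]
  if (length(m) == 0L)
    st_format(sprintf("malformed variable column header '%s'", h))
  list(name = trimws(m[2]),
       harvest = nzchar(m[3]),
       method = if (nzchar(trimws(m[4]))) trimws(m[4]) else NULL,
       date = if (nzchar(trimws(m[5]))) trimws(m[5]) else NULL)
}

# Read a TSV stream into (header, rows). Cells are kept verbatim; short rows
# are padded with "" to the header width.
st_read_tsv <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) {
    if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
      strsplit(text, "\n", fixed = TRUE)[[1]]
    else text
  } else {
    if (!file.exists(path)) st_format(sprintf("cannot read '%s'", path))
    readLines(path, encoding = "UTF-8", warn = FALSE)
  }
  lines <- sub("\r$", "", lines)
  lines <- lines[cumsum(nzchar(lines)) > 0]  # leading blank lines
  if (length(lines) == 0L) st_format("empty file: no header row")
  split1 <- function(l) strsplit(l, "\t", fixed = TRUE)[[1]]
  header <- trimws(split1(lines[1]))
  body <- lines[-1]
  keep <- nzchar(trimws(gsub("\t", "", body)))
  rows <- lapply(which(keep), function(i) {
    cells <- split1(body[i])
    length(cells) <- max(length(cells), length(header))
    cells[is.na(cells)] <- ""
    list(line = i + 1L, cells = trimws(cells))
  })
  list(header = header, rows = rows)
}
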