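# Wizard-style template export: pre-filled files for the lots already in the
# store, so users only complete the remaining cells before re-submission.

st_tsv_line <- function(cells) paste(cells, collapse = "\t")

#' Export a pre-filled file template
#'
#' Emits the header row of the requested format plus one pre-filled data row
#' per selected seed lot: the columns the store already knows (the lot itself,
#' its location, a deterministic \code{event_id}) are filled, everything else
#' — dates, quantities, variable columns — is left for the user. Because the
#' generated \code{event_id}s are deterministic, re-importing a template whose
#' events were already submitted is detected as a duplicate and skipped with a
#' warning rather than recorded twice.
#'
#' For \code{kind = "mixture"} all selected lots share one \code{event_id}
#' (one mixture of the whole selection); for \code{individual_measures} each
#' lot becomes a subject row.
#'
#' @param store a \code{seedlot_store}.
#' @param selection character vector of existing seed lot names.
#' @param kind one of the six [format_specs()] kinds.
#' @param path optional path to write the template to.
#' @return the template lines (header + rows), invisibly when written.
#' @export
export_template <- function(store, selection, kind, path = NULL) {
  spec <- format_specs(kind)
  if (length(selection) == 0L)
    st_incompatible("empty selection: nothing to export")
  if (!is.character(selection))
    st_incompatible(sprintf("a %s template is built from seed lot names", kind))
  lots <- lapply(selection, lot_row, store = store)
  locs <- vapply(lots, function(l) st_name_of(store, "location", l$location_id),
                 character(1))
  h <- spec$mandatory_headers
  blank <- function(lot, fill) {
    cells <- stats::setNames(rep("", length(h)), h)
    cells[names(fill)] <- unlist(fill)
    st_tsv_line(cells)
  }
  eid <- function(prefix, lot) paste0(prefix, "-", lot)
  rows <- switch(kind,
    reproduction = vapply(seq_along(selection), function(i)
      blank(selection[i], list(event_id = eid("repro", selection[i]),
                               sown_seed_lot = selection[i],
                               location = locs[i])), character(1)),
    cross = vapply(seq_along(selection), function(i)
      blank(selection[i], list(event_id = eid("cross", selection[i]),
                               mother_seed_lot = selection[i],
                               location = locs[i])), character(1)),
    selection = vapply(seq_along(selection), function(i)
      blank(selection[i], list(event_id = eid("selection", selection[i]),
                               parent_seed_lot = selection[i],
                               location = locs[i])), character(1)),
    mixture = {
      shared <- eid("mixture", sort(selection)[1])
      vapply(seq_along(selection), function(i)
        blank(selection[i], list(event_id = shared,
                                 parent_seed_lot = selection[i],
                                 location = locs[i])), character(1))
    },
    diffusion = vapply(seq_along(selection), function(i)
      blank(selection[i], list(event_id = eid("diffusion", selection[i]),
                               parent_seed_lot = selection[i])), character(1)),
    individual_measures = vapply(seq_along(selection), function(i)
      blank(selection[i], list(subject_seed_lot = selection[i])), character(1)))
  out <- c(st_tsv_line(h), rows)
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

#' Delete reproduction events listed in a file
#'
#' A reproduction file (typically an export of recorded relations) drives the
#' deletion: each row's \code{event_id} must resolve to an existing
#' reproduction event, otherwise the whole file is rejected and nothing is
#' deleted. Deletion is applied atomically via [delete_event()] per row; with
#' \code{cascade = TRUE} each event's whole downstream subtree goes with it
#' (rows whose event was already removed by an earlier row's cascade are
#' skipped).
#'
#' @param store a \code{seedlot_store}.
#' @param path,text the reproduction-format TSV (see [import_file()]).
#' @param cascade delete downstream events too.
#' @return an aggregated \code{deletion_report}.
#' @export
delete_from_file <- function(store, path = NULL, text = NULL, cascade = FALSE) {
  spec <- format_specs("reproduction")
  tsv <- st_read_tsv(path, text)
  if (!("event_id" %in% tsv$header))
    st_format("missing mandatory header(s): event_id")
  labs <- vapply(tsv$rows, function(r)
    r$cells[match("event_id", tsv$header)], character(1))
  ev <- store$tables$event
  known <- !is.na(ev$label)
  bad <- vapply(seq_along(labs), function(i) {
    hit <- ev$kind[known][ev$label[known] == labs[i]]
    length(hit) == 0L || hit[1] != "reproduction"
  }, logical(1))
  if (any(bad))
    st_unknown(sprintf("row(s) %s do not resolve to a recorded reproduction event: file rejected, nothing deleted",
                       paste(vapply(tsv$rows[bad], `[[`, integer(1), "line"),
                             collapse = ", ")))
  mode <- if (cascade) "cascade" else "alone"
  work <- store_clone(store)
  reports <- list()
  for (lab in labs) {
    if (!any(work$tables$event$label == lab, na.rm = TRUE)) next  # removed by an earlier cascade
    reports[[length(reports) + 1L]] <- delete_event(work, lab, mode)
  }
  st_commit(store, work)
  st_merge_reports(reports, mode)
}
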