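# Two-phase file import: the whole file is validated and applied against a
# scratch copy of the store, collecting every issue; only when no error at
# all was raised is the copy committed. A rejected import therefore leaves
# the store byte-identical.

st_new_report <- function() {
  structure(list(status = "ok", rows_read = 0L, events_created = 0L,
                 lots_created = 0L, data_points_created = 0L,
                 issues = data.frame(row = integer(), severity = character(),
                                     message = character(),
                                     stringsAsFactors = FALSE)),
            class = "import_report")
}

#' @export
print.import_report <- function(x, ...) {
  cat(sprintf("import %s: %d row(s) read, %d event(s), %d lot(s), %d data point(s) created\n",
              x$status, x$rows_read, x$events_created, x$lots_created,
              x$data_points_created))
  if (nrow(x$issues)) {
    iss <- x$issues[order(x$issues$row), ]
    for (i in seq_len(nrow(iss)))
      cat(sprintf("  row %d\t%s\t%s\n", iss$row[i], iss$severity[i], iss$message[i]))
  }
  invisible(x)
}

#' Machine-readable lines of an import report
#'
#' One issue per line: \code{row<TAB>severity<TAB>message}.
#' @param report an \code{import_report}.
#' @return character vector (possibly empty).
#' @export
report_lines <- function(report) {
  iss <- report$issues[order(report$issues$row), , drop = FALSE]
  sprintf("%d\t%s\t%s", iss$row, iss$severity, iss$message)
}

#' Import a tabulated event or measures file
#'
#' Validation is two-phase: every row is checked (and tentatively applied to a
#' scratch copy of the store) so that the report lists all problems at once,
#' and the store is mutated only when the file contains no error. Unknown
#' parent lots, malformed dates or quantities, wrong multiplicities and
#' duplicated event ids within the file are errors; unknown quantities,
#' auto-registered variables, re-imports of an already recorded event id
#' (skipped) and defaulted missing dates are warnings. A missing or unreadable
#' header is a \code{FormatError} condition, distinct from a rejected report.
#'
#' @param store a \code{seedlot_store}.
#' @param kind one of the six [format_specs()] kinds.
#' @param path path of a TSV file, or
#' @param text the file content as a character vector/string instead.
#' @param header_map optional named character vector remapping site-dialect
#'   header names to the canonical ones (names = file headers, values =
#'   canonical headers).
#' @return an \code{import_report}; \code{status} is \code{"rejected"} iff at
#'   least one issue has severity error, in which case nothing was changed.
#' @export
import_file <- function(store, kind, path = NULL, text = NULL,
                        header_map = NULL) {
  spec <- format_specs(kind)
  tsv <- st_read_tsv(path, text)
  header <- tsv$header
  if (!is.null(header_map)) {
    hit <- header %in% names(header_map)
    header[hit] <- unname(header_map[header[hit]])
  }
  missing <- setdiff(spec$mandatory_headers, header)
  if (length(missing))
    st_format(sprintf("missing mandatory header(s): %s",
                      paste(missing, collapse = ", ")))
  var_idx <- which(!(header %in% spec$mandatory_headers) & nzchar(header))
  var_cols <- lapply(header[var_idx], st_parse_var_header)

  rep <- st_new_report()
  rep$rows_read <- length(tsv$rows)
  issues <- list()
  note <- function(row, severity, message)
    issues[[length(issues) + 1L]] <<- data.frame(row = row, severity = severity,
                                                 message = message,
                                                 stringsAsFactors = FALSE)
  work <- store_clone(store)
  col <- function(cells, name) {
    i <- match(name, header)
    if (is.na(i) || i > length(cells)) "" else cells[i]
  }
  num_or <- function(v, row, what) {
    if (!nzchar(v)) return(NA_real_)
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) { note(row, "error", sprintf("%s: not a number ('%s')", what, v)); return(NA_real_) }
    if (x < 0) { note(row, "error", sprintf("%s: negative quantity (%s)", what, v)); return(NA_real_) }
    x
  }
  date_or <- function(v, row, what, default_year = NULL) {
    if (!nzchar(v)) {
      if (!is.null(default_year)) {
        note(row, "warning", sprintf("%s missing: defaulted to year %d", what, default_year))
        return(as.character(default_year))
      }
      note(row, "error", sprintf("%s is required", what))
      return(NULL)
    }
    tryCatch({ parse_date(v); v },
             seedtrace_error = function(e) { note(row, "error", sprintf("%s: %s", what, conditionMessage(e))); NULL })
  }
  lot_year <- function(name) {
    r <- st_row_by(work, "seed_lot", "name", name)
    if (nrow(r)) r$year[1] else NULL
  }
  ensure_actor <- function(nm) {
    if (!nzchar(nm)) return(NULL)
    if (nrow(st_row_by(work, "person", "name", nm)) == 0L)
      register_person(work, nm)
    nm
  }
  ensure_location <- function(nm, row) {
    if (!nzchar(nm)) { note(row, "error", "location is required"); return(NULL) }
    if (nrow(st_row_by(work, "location", "name", nm)) == 0L) {
      register_location(work, nm)
      note(row, "warning", sprintf("location '%s' auto-registered", nm))
    }
    nm
  }
  seen_labels <- character(0)
  check_label <- function(lab, row) {
    if (!nzchar(lab)) { note(row, "error", "event_id is required"); return(NA) }
    if (lab %in% seen_labels) {
      note(row, "error", sprintf("duplicate event_id '%s' within file", lab))
      return(NA)
    }
    seen_labels <<- c(seen_labels, lab)
    if (any(store$tables$event$label == lab, na.rm = TRUE)) {
      note(row, "warning", sprintf("event '%s' already recorded: row skipped", lab))
      return(FALSE)
    }
    TRUE
  }
  warned_vars <- character(0)
  # Attach the variable columns of one row. subjects: list(relation =
  # c(parent, child) or NULL, lot = name or NULL); level as registered.
  apply_vars <- function(cells, row, rel_subject = NULL, harvest_lot = NULL,
                         lot_subject = NULL, row_date = NULL,
                         individual = NA_integer_, level = "global") {
    for (j in seq_along(var_idx)) {
      vc <- var_cols[[j]]
      if (is.null(vc)) next
      val <- if (var_idx[j] <= length(cells)) cells[var_idx[j]] else ""
      if (!nzchar(val)) next
      if (nrow(st_row_by(work, "variable", "name", vc$name)) == 0L) {
        register_variable(work, vc$name, level = level)
        if (!(vc$name %in% warned_vars)) {
          warned_vars <<- c(warned_vars, vc$name)
          note(row, "warning", sprintf("variable '%s' auto-registered (%s level)",
                                       vc$name, level))
        }
      }
      dt <- if (!is.null(vc$date)) vc$date else row_date
      ok <- tryCatch({
        if (!is.null(lot_subject)) {
          add_raw_data(work, lot = lot_subject, variable = vc$name, value = val,
                       method = vc$method, date = dt, individual = individual)
        } else if (vc$harvest) {
          add_raw_data(work, lot = harvest_lot, variable = vc$name, value = val,
                       method = vc$method, date = dt, individual = individual)
        } else {
          add_raw_data(work, parent = rel_subject[1], child = rel_subject[2],
                       variable = vc$name, value = val, method = vc$method,
                       date = dt, individual = individual)
        }
        TRUE
      }, seedtrace_error = function(e) {
        note(row, "error", sprintf("column '%s': %s", vc$name, conditionMessage(e)))
        FALSE
      })
      if (ok) rep$data_points_created <- rep$data_points_created + 1L
    }
    rep <<- rep
  }
  run_event <- function(row, expr) {
    tryCatch({
      res <- expr()
      rep$events_created <<- rep$events_created + 1L
      rep$lots_created <<- rep$lots_created + length(res$children)
      res
    }, seedtrace_error = function(e) { note(row, "error", conditionMessage(e)); NULL })
  }

  rows <- tsv$rows
  for (r in rows) {
    if (sum(nzchar(r$cells)) && length(r$cells) > length(header) &&
        any(nzchar(r$cells[(length(header) + 1L):length(r$cells)])))
      note(r$line, "error", "row has more cells than the header")
  }

  if (kind %in% c("reproduction", "cross", "diffusion")) {
    for (r in rows) {
      row <- r$line; cells <- r$cells
      lab <- check_label(col(cells, "event_id"), row)
      if (is.na(lab) || identical(lab, FALSE)) next
      if (kind == "reproduction") {
        sown <- col(cells, "sown_seed_lot")
        if (!nzchar(sown)) { note(row, "error", "sown_seed_lot is required"); next }
        d <- date_or(col(cells, "sowing_date"), row, "sowing_date",
                     default_year = lot_year(sown))
        loc <- ensure_location(col(cells, "location"), row)
        if (is.null(d) || is.null(loc)) next
        qs <- num_or(col(cells, "quantity_sown_g"), row, "quantity_sown_g")
        if (is.na(qs) && !nzchar(col(cells, "quantity_sown_g")))
          note(row, "warning", "quantity_sown_g unknown: no ledger debit")
        qh <- num_or(col(cells, "quantity_harvested_g"), row, "quantity_harvested_g")
        hd <- col(cells, "harvest_date")
        if (nzchar(hd)) { hd <- date_or(hd, row, "harvest_date"); if (is.null(hd)) next } else hd <- NULL
        res <- run_event(row, function()
          record_reproduction(work, sown, d, loc, ensure_actor(col(cells, "actor")),
                              qs, hd, qh, event_label = col(cells, "event_id")))
        if (!is.null(res))
          apply_vars(cells, row, rel_subject = c(sown, res$children[1]),
                     harvest_lot = res$children[1], row_date = d)
      } else if (kind == "cross") {
        mo <- col(cells, "mother_seed_lot"); fa <- col(cells, "father_seed_lot")
        if (!nzchar(mo) || !nzchar(fa)) { note(row, "error", "mother_seed_lot and father_seed_lot are required"); next }
        d <- date_or(col(cells, "date"), row, "date", default_year = lot_year(mo))
        loc <- ensure_location(col(cells, "location"), row)
        if (is.null(d) || is.null(loc)) next
        res <- run_event(row, function()
          record_cross(work, mo, fa, d, loc, ensure_actor(col(cells, "actor")),
                       event_label = col(cells, "event_id")))
        if (!is.null(res))
          apply_vars(cells, row, rel_subject = c(mo, res$children[1]),
                     harvest_lot = res$children[1], row_date = d)
      } else {
        par <- col(cells, "parent_seed_lot")
        if (!nzchar(par)) { note(row, "error", "parent_seed_lot is required"); next }
        d <- date_or(col(cells, "date"), row, "date", default_year = lot_year(par))
        rloc <- col(cells, "recipient_location")
        if (!nzchar(rloc)) { note(row, "error", "recipient_location is required"); next }
        if (nrow(st_row_by(work, "location", "name", rloc)) == 0L) {
          register_location(work, rloc)
          note(row, "warning", sprintf("location '%s' auto-registered", rloc))
        }
        rper <- col(cells, "recipient_person")
        if (nzchar(rper) && nrow(st_row_by(work, "person", "name", rper)) == 0L)
          register_person(work, rper)
        q <- num_or(col(cells, "quantity_g"), row, "quantity_g")
        if (is.na(q) && !nzchar(col(cells, "quantity_g")))
          note(row, "warning", "quantity_g unknown: no ledger debit")
        if (is.null(d)) next
        res <- run_event(row, function()
          record_diffusion(work, par, rloc, if (nzchar(rper)) rper else NULL,
                           q, d, event_label = col(cells, "event_id")))
        if (!is.null(res))
          apply_vars(cells, row, rel_subject = c(par, res$children[1]),
                     harvest_lot = res$children[1], row_date = d)
      }
    }
  } else if (kind %in% c("selection", "mixture")) {
    # rows sharing event_id form one event
    labs <- vapply(rows, function(r) col(r$cells, "event_id"), character(1))
    for (lab in unique(labs)) {
      grp <- rows[labs == lab]
      row <- grp[[1]]$line
      st <- check_label(lab, row)
      if (is.na(st) || identical(st, FALSE)) next
      par <- vapply(grp, function(r) col(r$cells, "parent_seed_lot"), character(1))
      q <- vapply(seq_along(grp), function(i)
        num_or(col(grp[[i]]$cells,
                   if (kind == "mixture") "quantity_used_g" else "quantity_used_g"),
               grp[[i]]$line, "quantity_used_g"), numeric(1))
      d <- date_or(col(grp[[1]]$cells, "date"), row, "date",
                   default_year = lot_year(par[1]))
      loc <- ensure_location(col(grp[[1]]$cells, "location"), row)
      if (is.null(d) || is.null(loc)) next
      if (any(!nzchar(par))) { note(row, "error", "parent_seed_lot is required"); next }
      if (kind == "mixture") {
        res <- run_event(row, function()
          record_mixture(work, par, d, loc,
                         ensure_actor(col(grp[[1]]$cells, "actor")),
                         quantities_g = q, event_label = lab))
        if (!is.null(res))
          for (i in seq_along(grp))
            apply_vars(grp[[i]]$cells, grp[[i]]$line,
                       rel_subject = c(par[i], res$children[1]),
                       harvest_lot = res$children[1], row_date = d)
      } else {
        if (length(unique(par)) > 1L) {
          note(row, "error", sprintf("selection event '%s' lists several parent lots", lab)); next
        }
        sel <- vapply(grp, function(r) col(r$cells, "selection_label"), character(1))
        if (any(!nzchar(sel))) { note(row, "error", "selection_label is required"); next }
        res <- run_event(row, function()
          record_selection(work, par[1], sel, d, loc,
                           ensure_actor(col(grp[[1]]$cells, "actor")),
                           quantity_used_g = q, event_label = lab))
        if (!is.null(res))
          for (i in seq_along(grp))
            apply_vars(grp[[i]]$cells, grp[[i]]$line,
                       rel_subject = c(par[1], res$children[i]),
                       harvest_lot = res$children[i], row_date = d)
      }
    }
  } else {  # individual_measures
    for (r in rows) {
      row <- r$line; cells <- r$cells
      subj <- col(cells, "subject_seed_lot")
      if (!nzchar(subj)) { note(row, "error", "subject_seed_lot is required"); next }
      if (nrow(st_row_by(work, "seed_lot", "name", subj)) == 0L) {
        note(row, "error", sprintf("unknown seed lot '%s'", subj)); next
      }
      idx <- suppressWarnings(as.integer(col(cells, "individual_index")))
      if (is.na(idx) || idx < 1L) {
        note(row, "error", "individual_index must be a positive integer"); next
      }
      d <- col(cells, "date")
      if (nzchar(d)) { d <- date_or(d, row, "date"); if (is.null(d)) next } else d <- NULL
      apply_vars(cells, row, lot_subject = subj, row_date = d,
                 individual = idx, level = "individual")
    }
  }

  if (length(issues)) rep$issues <- do.call(rbind, issues)
  if (any(rep$issues$severity == "error")) {
    rep$status <- "rejected"
    rep$events_created <- 0L
    rep$lots_created <- 0L
    rep$data_points_created <- 0L
  } else {
    st_commit(store, work)
  }
  rep
}
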