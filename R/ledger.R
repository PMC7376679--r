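# Stock accounting: every lot's stock is reconstructed by replaying a totally
# ordered ledger of (initial credit, relation debits, inventory resets).
# Nothing is ever clamped; negative balances stay visible as warnings.

st_kind_rank <- c(initial = 0L, debit = 1L, inventory = 2L)

#' Full stock history of a seed lot
#'
#' Entries are ordered by (date, kind, source id) with the tie rule
#' initial < debit < inventory: an inventory taken the day of a sowing
#' reflects the post-sowing stock. The initial credit is dated at the creating
#' event when the lot was harvested, otherwise July 1 of the creation year;
#' it is absent when the initial quantity is unknown (replay then starts from
#' zero and the history carries an \code{unknown_initial} warning). Every
#' relation using the lot as parent with a known quantity is a debit; a
#' relation with unknown quantity contributes nothing but flags the history
#' \code{approximate}. An inventory entry resets the balance to its measured
#' value regardless of what preceded it.
#'
#' @param store a \code{seedlot_store}.
#' @param lot lot name.
#' @return a data.frame of class \code{stock_history} with columns date, kind,
#'   amount_g, balance_after_g, source; attribute \code{warnings} is a
#'   character vector among \code{unknown_initial}, \code{negative_balance},
#'   \code{approximate}.
#' @export
stock_history <- function(store, lot) {
  lrow <- lot_row(store, lot)
  warnings <- character(0)

  entries <- data.frame(date = as.Date(character()), kind = character(),
                        amount_g = numeric(), source = character(),
                        source_id = integer(), stringsAsFactors = FALSE)
  add <- function(date, kind, amount, source, sid) {
    entries[nrow(entries) + 1L, ] <<- list(date, kind, amount, source, sid)
  }

  if (!is.na(lrow$initial_g)) {
    rel <- store$tables$relation
    ev <- store$tables$event
    making <- rel[rel$child_id == lrow$id, , drop = FALSE]
    d0 <- if (nrow(making)) {
      min(ev$date[match(making$event_id, ev$id)])
    } else as.Date(sprintf("%04d-07-01", lrow$year))
    add(d0, "initial", lrow$initial_g, paste0("lot:", lrow$name), 0L)
  }

  rel <- store$tables$relation
  out <- rel[rel$parent_id == lrow$id, , drop = FALSE]
  if (nrow(out)) {
    ev <- store$tables$event
    evr <- ev[match(out$event_id, ev$id), , drop = FALSE]
    for (i in seq_len(nrow(out))) {
      if (is.na(out$quantity_g[i])) {
        warnings <- union(warnings, "approximate")
      } else {
        add(evr$date[i], "debit", out$quantity_g[i],
            paste0(evr$kind[i], ":", evr$label[i]), out$id[i])
      }
    }
  }

  inv <- store$tables$inventory
  inv <- inv[inv$lot_id == lrow$id, , drop = FALSE]
  for (i in seq_len(nrow(inv)))
    add(inv$date[i], "inventory", inv$measured_g[i],
        paste0("inventory:", inv$id[i]), inv$id[i])

  entries <- entries[order(entries$date, st_kind_rank[entries$kind],
                           entries$source_id), , drop = FALSE]
  if (is.na(lrow$initial_g) && nrow(entries))
    warnings <- union(warnings, "unknown_initial")

  bal <- 0
  balance <- numeric(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    bal <- switch(entries$kind[i],
                  initial = entries$amount_g[i],
                  debit = bal - entries$amount_g[i],
                  inventory = entries$amount_g[i])
    bal <- st_round_g(bal)
    balance[i] <- bal
  }
  entries$balance_after_g <- balance
  if (any(balance < 0)) warnings <- union(warnings, "negative_balance")

  out <- entries[, c("date", "kind", "amount_g", "balance_after_g", "source")]
  rownames(out) <- NULL
  structure(out, class = c("stock_history", "data.frame"),
            warnings = warnings, lot = lrow$name,
            initial_known = !is.na(lrow$initial_g))
}

#' Current stock of a seed lot
#'
#' The balance after the last ledger entry at or before \code{as_of}
#' (default: all entries). A lot with no applicable entries has unknown stock
#' (\code{NA}), which is distinct from a stock of 0 grams.
#'
#' @param store a \code{seedlot_store}.
#' @param lot lot name.
#' @param as_of optional cut-off date (any accepted dialect, or a Date).
#' @return list(grams, warnings); grams is \code{NA} when unknown.
#' @export
current_stock <- function(store, lot, as_of = NULL) {
  h <- stock_history(store, lot)
  w <- attr(h, "warnings")
  if (!is.null(as_of)) {
    cutoff <- if (inherits(as_of, "Date")) as_of else parse_date(as_of)$date
    h <- h[h$date <= cutoff, , drop = FALSE]
  }
  if (nrow(h) == 0L)
    return(list(grams = NA_real_, warnings = union(w, "no_entries")))
  list(grams = h$balance_after_g[nrow(h)], warnings = w)
}

#' @export
print.stock_history <- function(x, ...) {
  cat(sprintf("stock history of %s (%d entries)\n", attr(x, "lot"), nrow(x)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  w <- attr(x, "warnings")
  if (length(w)) cat("warnings:", paste(w, collapse = ", "), "\n")
  invisible(x)
}

#' Write a table as TSV
#'
#' Plain UTF-8 tab-separated output used for stock histories, query tables and
#' card sections. Missing values are written as empty cells.
#' @param x a data.frame.
#' @param path file path, or \code{""} for stdout.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(x, path = "") {
  df <- as.data.frame(x)
  for (cn in names(df)) if (inherits(df[[cn]], "Date"))
    df[[cn]] <- format(df[[cn]], "%Y-%m-%d")
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
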