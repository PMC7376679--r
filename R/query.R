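# Filtered data retrieval (three result tables), seed-lot and relation cards,
# and prefix search with auto-complete semantics.

# Uniform data row for one raw_data record: subject, variable, method, date,
# value, level (+ hidden join columns used by the filter).
st_data_rows <- function(store) {
  rd <- store$tables$raw_data
  if (nrow(rd) == 0L) {
    return(data.frame(subject = character(), variable = character(),
                      method = character(), date = character(),
                      value = character(), level = character(),
                      individual = integer(),
                      germplasm = character(), species = character(),
                      location = character(), actor = character(),
                      project = character(), fdate = as.Date(character()),
                      subject_type = character(), stringsAsFactors = FALSE))
  }
  vt <- store$tables$variable
  lot <- store$tables$seed_lot
  rel <- store$tables$relation
  ev <- store$tables$event
  germ <- store$tables$germplasm

  vrow <- vt[match(rd$variable_id, vt$id), , drop = FALSE]
  is_lot <- rd$subject_type == "lot"
  lot_id <- ifelse(is_lot, rd$subject_id,
                   rel$child_id[match(rd$subject_id, rel$id)])
  lrow <- lot[match(lot_id, lot$id), , drop = FALSE]
  grow <- germ[match(lrow$germplasm_id, germ$id), , drop = FALSE]
  ev_id <- ifelse(is_lot, NA_integer_,
                  rel$event_id[match(rd$subject_id, rel$id)])
  erow <- ev[match(ev_id, ev$id), , drop = FALSE]

  subject <- ifelse(is_lot, lrow$name,
                    paste0(st_name_of(store, "seed_lot",
                                      rel$parent_id[match(rd$subject_id, rel$id)]),
                           " -> ", lrow$name))
  # filtering date: the measure's own date, falling back to the event date
  fdate <- as.Date(ifelse(!is.na(rd$date), rd$date, erow$date),
                   origin = "1970-01-01")
  data.frame(
    subject = subject,
    variable = vrow$name,
    method = st_name_of(store, "method", rd$method_id),
    date = ifelse(is.na(rd$date), NA_character_,
                  st_format_date(rd$date, rd$date_precision)),
    value = rd$value,
    level = vrow$level,
    individual = rd$individual,
    germplasm = grow$name, species = grow$species,
    location = st_name_of(store, "location", lrow$location_id),
    actor = st_name_of(store, "person", erow$actor_id),
    project = erow$project,
    fdate = fdate,
    subject_type = rd$subject_type,
    stringsAsFactors = FALSE)
}

#' Query measured data into three tables
#'
#' All recorded data points matching a conjunctive filter, split the way
#' results are always presented: table 1 holds data attached to seed lots,
#' table 2 data attached to relations at global level, table 3 all
#' individual-level data. An empty filter returns everything; strengthening a
#' filter can only shrink each table.
#'
#' @param store a \code{seedlot_store}.
#' @param germplasm,species,location,actor,variable,project optional exact
#'   filters (the lot attributes for lot-attached data, the event's for
#'   relation-attached data).
#' @param date_range optional length-2 vector (start, end) in any accepted
#'   date dialect; matched against each measure's own date, falling back to
#'   the event date.
#' @return an object of class \code{query_result}: list of three data.frames
#'   \code{seed_lot_table}, \code{relation_table}, \code{individual_table},
#'   each with columns subject, variable, method, date, value, level,
#'   individual.
#' @export
query_data <- function(store, germplasm = NULL, species = NULL,
                       location = NULL, actor = NULL, variable = NULL,
                       project = NULL, date_range = NULL) {
  d <- st_data_rows(store)
  keep <- rep(TRUE, nrow(d))
  flt <- function(colv, val) if (is.null(val)) TRUE else !is.na(colv) & colv == val
  keep <- keep & flt(d$germplasm, germplasm) & flt(d$species, species) &
    flt(d$location, location) & flt(d$actor, actor) &
    flt(d$variable, variable) & flt(d$project, project)
  if (!is.null(date_range)) {
    if (length(date_range) != 2L) st_validation("date_range must be (start, end)")
    from <- parse_date(as.character(date_range[1]))$date
    to <- parse_date(as.character(date_range[2]))$date
    if (from > to) st_validation("date_range start is after its end")
    keep <- keep & !is.na(d$fdate) & d$fdate >= from & d$fdate <= to
  }
  d <- d[keep, , drop = FALSE]
  cols <- c("subject", "variable", "method", "date", "value", "level", "individual")
  tidy <- function(x) { x <- x[, cols, drop = FALSE]; rownames(x) <- NULL; x }
  structure(list(
    seed_lot_table = tidy(d[d$subject_type == "lot" & d$level == "global", , drop = FALSE]),
    relation_table = tidy(d[d$subject_type == "relation" & d$level == "global", , drop = FALSE]),
    individual_table = tidy(d[d$level == "individual", , drop = FALSE])),
    class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  nm <- c(seed_lot_table = "seed-lot data", relation_table = "relation data",
          individual_table = "individual data")
  for (tn in names(nm)) {
    cat(sprintf("## %s (%d row(s))\n", nm[[tn]], nrow(x[[tn]])))
    if (nrow(x[[tn]])) print.data.frame(x[[tn]], row.names = FALSE)
  }
  invisible(x)
}

#' Seed-lot card
#'
#' The aggregated view of one lot, in four sections: identity (name, species,
#' germplasm, location, year), history (the event that created it and every
#' event using it as a parent), attached data, and stock (current level plus
#' the full ledger).
#'
#' @param store a \code{seedlot_store}.
#' @param lot lot name.
#' @return an object of class \code{seed_lot_card} with elements
#'   \code{identity}, \code{history}, \code{data}, \code{stock}.
#' @export
seed_lot_card <- function(store, lot) {
  lrow <- lot_row(store, lot)
  germ <- store$tables$germplasm[
    match(lrow$germplasm_id, store$tables$germplasm$id), , drop = FALSE]
  identity <- data.frame(
    field = c("name", "species", "germplasm", "location", "year", "origin"),
    value = c(lrow$name, germ$species, germ$name,
              st_name_of(store, "location", lrow$location_id),
              as.character(lrow$year),
              if (lrow$origin) "origin lot" else "created by an event"),
    stringsAsFactors = FALSE)
  up <- parents(store, lot)
  down <- children(store, lot)
  history <- rbind(
    if (nrow(up)) cbind(role = "created by", up) else NULL,
    if (nrow(down)) cbind(role = "used by", down) else NULL)
  if (is.null(history))
    history <- data.frame(role = "no creating event", lot = NA_character_,
                          relation_id = NA_integer_, event = NA_character_,
                          kind = NA_character_, date = NA_character_,
                          location = NA_character_, quantity_g = NA_real_,
                          stringsAsFactors = FALSE)
  d <- st_data_rows(store)
  d <- d[d$subject_type == "lot" & d$subject == lrow$name,
         c("variable", "method", "date", "value", "level", "individual"),
         drop = FALSE]
  rownames(d) <- NULL
  stock <- list(current = current_stock(store, lot),
                history = stock_history(store, lot))
  structure(list(identity = identity, history = history, data = d,
                 stock = stock, lot = lrow$name),
            class = "seed_lot_card")
}

#' @export
print.seed_lot_card <- function(x, ...) {
  cat(sprintf("== seed lot card: %s ==\n", x$lot))
  cat("-- identity --\n"); print.data.frame(x$identity, row.names = FALSE)
  cat("-- history --\n"); print.data.frame(x$history, row.names = FALSE)
  cat(sprintf("-- data (%d point(s)) --\n", nrow(x$data)))
  if (nrow(x$data)) print.data.frame(x$data, row.names = FALSE)
  g <- x$stock$current$grams
  cat(sprintf("-- stock: %s --\n",
              if (is.na(g)) "unknown" else sprintf("%.1f g", g)))
  print(x$stock$history)
  invisible(x)
}

#' Relation card
#'
#' The aggregated view of one parent/child link, in two sections: the
#' relation info (parent, child, owning event, grams used) and the data
#' measured on it, at global and individual level. When the same pair is
#' linked by several relations (repeated events across years) all are listed,
#' newest first.
#'
#' @param store a \code{seedlot_store}.
#' @param parent,child lot names.
#' @return an object of class \code{relation_card} with elements \code{info}
#'   and \code{data}.
#' @export
relation_card <- function(store, parent, child) {
  pid <- lot_row(store, parent)$id
  cid <- lot_row(store, child)$id
  rel <- store$tables$relation
  hit <- rel[rel$parent_id == pid & rel$child_id == cid, , drop = FALSE]
  if (nrow(hit) == 0L)
    st_unknown(sprintf("no relation %s -> %s", parent, child))
  ev <- store$tables$event[match(hit$event_id, store$tables$event$id), , drop = FALSE]
  ord <- order(ev$date, decreasing = TRUE)
  info <- data.frame(parent = parent, child = child,
                     event = ev$label[ord], kind = ev$kind[ord],
                     date = st_format_date(ev$date[ord], ev$date_precision[ord]),
                     location = st_name_of(store, "location", ev$location_id[ord]),
                     quantity_g = hit$quantity_g[ord],
                     stringsAsFactors = FALSE)
  d <- st_data_rows(store)
  d <- d[d$subject_type == "relation" & d$subject == paste0(parent, " -> ", child),
         c("variable", "method", "date", "value", "level", "individual"),
         drop = FALSE]
  rownames(d) <- NULL
  structure(list(info = info, data = d), class = "relation_card")
}

#' @export
print.relation_card <- function(x, ...) {
  cat(sprintf("== relation card: %s -> %s ==\n", x$info$parent[1], x$info$child[1]))
  cat("-- relation --\n"); print.data.frame(x$info, row.names = FALSE)
  cat(sprintf("-- data (%d point(s)) --\n", nrow(x$data)))
  if (nrow(x$data)) print.data.frame(x$data, row.names = FALSE)
  invisible(x)
}

#' Export a card's sections as TSV files
#'
#' Writes one TSV per section next to \code{prefix}
#' (\code{<prefix>_<section>.tsv}).
#' @param card a \code{seed_lot_card} or \code{relation_card}.
#' @param prefix path prefix for the output files.
#' @return character vector of the files written.
#' @export
card_export <- function(card, prefix) {
  sections <- if (inherits(card, "seed_lot_card")) {
    list(identity = card$identity, history = card$history, data = card$data,
         stock = as.data.frame(card$stock$history))
  } else if (inherits(card, "relation_card")) {
    list(info = card$info, data = card$data)
  } else st_validation("not a card")
  paths <- character(0)
  for (sn in names(sections)) {
    p <- paste0(prefix, "_", sn, ".tsv")
    write_tsv(sections[[sn]], p)
    paths <- c(paths, p)
  }
  paths
}

#' Auto-complete search over lots, germplasms and relations
#'
#' Case-insensitive matching ranked exact match first, then prefix matches,
#' then substring matches, alphabetical within each rank. Extending the query
#' string can only narrow the result.
#'
#' @param store a \code{seedlot_store}.
#' @param prefix query string, at least one character.
#' @return data.frame(name, type, rank) ordered by rank.
#' @export
search_store <- function(store, prefix) {
  if (!is.character(prefix) || length(prefix) != 1L || !nzchar(prefix))
    st_validation("search needs a query of at least one character")
  rel <- store$tables$relation
  cand <- rbind(
    data.frame(name = store$tables$seed_lot$name, type = "seed_lot",
               stringsAsFactors = FALSE),
    data.frame(name = store$tables$germplasm$name, type = "germplasm",
               stringsAsFactors = FALSE),
    if (nrow(rel)) data.frame(
      name = paste0(st_name_of(store, "seed_lot", rel$parent_id), " -> ",
                    st_name_of(store, "seed_lot", rel$child_id)),
      type = "relation", stringsAsFactors = FALSE))
  if (is.null(cand) || nrow(cand) == 0L)
    return(data.frame(name = character(), type = character(), rank = integer(),
                      stringsAsFactors = FALSE))
  lo <- tolower(cand$name); q <- tolower(prefix)
  rank <- ifelse(lo == q, 1L,
                 ifelse(startsWith(lo, q), 2L,
                        ifelse(grepl(q, lo, fixed = TRUE), 3L, NA_integer_)))
  out <- cand[!is.na(rank), , drop = FALSE]
  out$rank <- rank[!is.na(rank)]
  out <- out[order(out$rank, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
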