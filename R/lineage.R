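# Pedigree traversal over the relation DAG: adjacency, reachability,
# generation counting and alone/cascade deletion of event subtrees.

# Relations joined to their event rows, for one lot as child (parents) or
# parent (children). Ordered by event date, then event id.
st_adjacent <- function(store, lot, side = c("parents", "children")) {
  side <- match.arg(side)
  lrow <- lot_row(store, lot)
  rel <- store$tables$relation
  hit <- if (side == "parents") rel$child_id == lrow$id else rel$parent_id == lrow$id
  rel <- rel[hit, , drop = FALSE]
  ev <- store$tables$event[match(rel$event_id, store$tables$event$id), , drop = FALSE]
  other_id <- if (side == "parents") rel$parent_id else rel$child_id
  out <- data.frame(
    lot = st_name_of(store, "seed_lot", other_id),
    relation_id = rel$id,
    event = ev$label, kind = ev$kind,
    date = st_format_date(ev$date, ev$date_precision),
    location = st_name_of(store, "location", ev$location_id),
    quantity_g = rel$quantity_g,
    stringsAsFactors = FALSE)
  out[order(ev$date, ev$id), , drop = FALSE]
}

#' Direct parents and children of a seed lot
#'
#' One row per relation the lot takes part in, joined with the owning event,
#' ordered by event date. An origin lot has no parents; an unused lot no
#' children.
#' @param store a \code{seedlot_store}.
#' @param lot lot name.
#' @return a data.frame with columns lot, relation_id, event, kind, date,
#'   location, quantity_g.
#' @export
parents <- function(store, lot) st_adjacent(store, lot, "parents")

#' @rdname parents
#' @export
children <- function(store, lot) st_adjacent(store, lot, "children")

# BFS over relations; direction "up" (ancestors) or "down" (descendants).
st_reach <- function(store, lot_id, direction, max_depth = Inf) {
  rel <- store$tables$relation
  seen <- integer(0)
  rel_ids <- integer(0)
  frontier <- lot_id
  depth <- 0
  while (length(frontier) && depth < max_depth) {
    hit <- if (direction == "up") rel$child_id %in% frontier else rel$parent_id %in% frontier
    nxt <- if (direction == "up") rel$parent_id[hit] else rel$child_id[hit]
    rel_ids <- union(rel_ids, rel$id[hit])
    frontier <- setdiff(unique(nxt), c(seen, lot_id))
    seen <- union(seen, frontier)
    depth <- depth + 1
  }
  list(lot_ids = seen, relation_ids = rel_ids)
}

#' Ancestor / descendant subgraph of a seed lot
#'
#' Breadth-first traversal over the relations, upwards (ancestors) or
#' downwards (descendants). With \code{max_depth = 1} ancestors reduce to the
#' direct parents.
#' @param store a \code{seedlot_store}.
#' @param lot lot name.
#' @param max_depth traversal depth limit (default unlimited).
#' @return a list with \code{lots} (character, excluding \code{lot} itself)
#'   and \code{relations} (the traversed relation rows).
#' @export
ancestors <- function(store, lot, max_depth = Inf) {
  r <- st_reach(store, lot_row(store, lot)$id, "up", max_depth)
  list(lots = sort(st_name_of(store, "seed_lot", r$lot_ids)),
       relations = store$tables$relation[
         store$tables$relation$id %in% r$relation_ids, , drop = FALSE])
}

#' @rdname ancestors
#' @export
descendants <- function(store, lot, max_depth = Inf) {
  r <- st_reach(store, lot_row(store, lot)$id, "down", max_depth)
  list(lots = sort(st_name_of(store, "seed_lot", r$lot_ids)),
       relations = store$tables$relation[
         store$tables$relation$id %in% r$relation_ids, , drop = FALSE])
}

#' Generation number of a seed lot
#'
#' \code{total} counts, along the deepest ancestry path, the reproduction
#' events since the lot's germplasm came into being: a cross or mixture event
#' resets the count to zero, selection and diffusion events pass it through
#' unchanged. \code{local} is the length of the maximal trailing run of
#' reproduction events performed at the lot's own stock location; a diffusion
#' (or any cross/mixture) breaks the run, a selection at the same location is
#' transparent. \code{quality} is \code{"exact"} unless some ancestry path
#' ends at a lot whose history is known to be truncated (\code{origin =
#' FALSE} with no recorded parents), in which case the numbers are lower
#' bounds and quality is \code{"minimum"}.
#'
#' @param store a \code{seedlot_store}.
#' @param lot lot name.
#' @return an object of class \code{generation_info}: list(total, local,
#'   quality).
#' @export
generation <- function(store, lot) {
  lrow <- lot_row(store, lot)
  rel <- store$tables$relation
  ev <- store$tables$event
  cache <- new.env(parent = emptyenv())

  prels <- function(id) {
    r <- rel[rel$child_id == id, , drop = FALSE]
    cbind(r, kind = ev$kind[match(r$event_id, ev$id)],
          ev_loc = ev$location_id[match(r$event_id, ev$id)])
  }
  total <- function(id) {
    key <- paste0("t", id)
    if (!is.null(cache[[key]])) return(cache[[key]])
    pr <- prels(id)
    val <- if (nrow(pr) == 0L) 0L else max(vapply(seq_len(nrow(pr)), function(i) {
      switch(pr$kind[i],
             cross = 0L, mixture = 0L,
             reproduction = 1L + total(pr$parent_id[i]),
             total(pr$parent_id[i]))
    }, integer(1)))
    cache[[key]] <- val
    val
  }
  local_run <- function(id, loc) {
    key <- paste0("l", id)
    if (!is.null(cache[[key]])) return(cache[[key]])
    pr <- prels(id)
    val <- if (nrow(pr) == 0L) 0L else max(vapply(seq_len(nrow(pr)), function(i) {
      if (pr$kind[i] == "reproduction" && pr$ev_loc[i] == loc)
        1L + local_run(pr$parent_id[i], loc)
      else if (pr$kind[i] == "selection" && pr$ev_loc[i] == loc)
        local_run(pr$parent_id[i], loc)
      else 0L
    }, integer(1)))
    cache[[key]] <- val
    val
  }
  truncated <- function(id) {
    key <- paste0("q", id)
    if (!is.null(cache[[key]])) return(cache[[key]])
    pr <- prels(id)
    val <- if (nrow(pr) == 0L) {
      !lot_row_by_id(store, id)$origin
    } else any(vapply(pr$parent_id, truncated, logical(1)))
    cache[[key]] <- val
    val
  }
  structure(list(total = total(lrow$id),
                 local = local_run(lrow$id, lrow$location_id),
                 quality = if (truncated(lrow$id)) "minimum" else "exact"),
            class = "generation_info")
}

#' @export
print.generation_info <- function(x, ...) {
  cat(sprintf("generation: total %d, local %d (%s)\n", x$total, x$local, x$quality))
  invisible(x)
}

#' Delete an event, alone or in cascade
#'
#' \code{mode = "alone"} removes the event, its relations and its output
#' lot(s) — refused when a downstream event already uses one of those lots.
#' \code{mode = "cascade"} additionally removes every event reachable through
#' the output lots' descendants, all lots those events created, and every
#' measured data point or inventory attached to anything removed. The store is
#' referentially intact afterwards.
#'
#' @param store a \code{seedlot_store}.
#' @param event event label (the external \code{event_id}).
#' @param mode \code{"alone"} or \code{"cascade"}.
#' @return a \code{deletion_report}: counts of events, lots and data points
#'   deleted.
#' @export
delete_event <- function(store, event, mode = c("alone", "cascade")) {
  mode <- match.arg(mode)
  ev <- store$tables$event
  eid <- ev$id[!is.na(ev$label) & ev$label == event]
  if (length(eid) == 0L) st_unknown(sprintf("unknown event '%s'", event))
  rel <- store$tables$relation

  del_events <- eid
  del_lots <- rel$child_id[rel$event_id %in% eid]
  if (mode == "alone") {
    downstream <- rel$event_id[rel$parent_id %in% del_lots]
    if (length(downstream))
      st_downstream(sprintf(
        "event '%s' has %d downstream relation(s); use cascade", event,
        length(downstream)))
  } else {
    repeat {
      more_ev <- setdiff(unique(rel$event_id[rel$parent_id %in% del_lots]), del_events)
      if (!length(more_ev)) break
      del_events <- c(del_events, more_ev)
      del_lots <- union(del_lots, rel$child_id[rel$event_id %in% more_ev])
    }
  }
  del_rel <- rel$id[rel$event_id %in% del_events]
  rd <- store$tables$raw_data
  drop_rd <- (rd$subject_type == "lot" & rd$subject_id %in% del_lots) |
    (rd$subject_type == "relation" & rd$subject_id %in% del_rel)
  inv <- store$tables$inventory
  drop_inv <- inv$lot_id %in% del_lots

  store$tables$raw_data <- rd[!drop_rd, , drop = FALSE]
  store$tables$inventory <- inv[!drop_inv, , drop = FALSE]
  store$tables$relation <- rel[!(rel$id %in% del_rel), , drop = FALSE]
  store$tables$event <- ev[!(ev$id %in% del_events), , drop = FALSE]
  store$tables$seed_lot <-
    store$tables$seed_lot[!(store$tables$seed_lot$id %in% del_lots), , drop = FALSE]

  structure(list(events_deleted = length(del_events),
                 lots_deleted = length(del_lots),
                 data_deleted = sum(drop_rd),
                 mode = mode, root = event),
            class = "deletion_report")
}

#' @export
print.deletion_report <- function(x, ...) {
  cat(sprintf("deletion (%s) from '%s': %d event(s), %d lot(s), %d data point(s) removed\n",
              x$mode, x$root, x$events_deleted, x$lots_deleted, x$data_deleted))
  invisible(x)
}

# Merge per-row deletion reports from a deletion file into one aggregate.
st_merge_reports <- function(reports, mode) {
  structure(list(
    events_deleted = sum(vapply(reports, `[[`, integer(1), "events_deleted")),
    lots_deleted = sum(vapply(reports, `[[`, integer(1), "lots_deleted")),
    data_deleted = sum(vapply(reports, `[[`, integer(1), "data_deleted")),
    mode = mode, root = sprintf("%d file row(s)", length(reports))),
    class = "deletion_report")
}
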