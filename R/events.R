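# Event recording: the five typed events that link seed lots. Each event owns
# one relation per parent lot and automatically creates (and names) its output
# lot(s).

st_event_kinds <- c("reproduction", "cross", "selection", "mixture", "diffusion")

#' The five event kinds
#'
#' Every relation between two seed lots belongs to an event of exactly one of
#' these kinds: reproduction (sow and harvest, same germplasm), cross
#' (controlled mating of two parents, new germplasm), selection (derivative
#' lot extracted from a parent), mixture (several parents blended into one new
#' lot; also represents open pollination), diffusion (seed transferred to
#' another actor/location).
#' @return character vector of the five kind names.
#' @export
event_kinds <- function() st_event_kinds

#' Name an automatically created seed lot
#'
#' Output lots are named \code{<germplasm>_<location>_<year>}; underscores
#' inside a component are mapped to \code{"-"} so the pattern stays parseable,
#' and a collision with an existing name appends \code{_2}, \code{_3}, ...
#' The result is deterministic for a given store state.
#'
#' @param store a \code{seedlot_store}.
#' @param germplasm,location component names (need not be registered yet).
#' @param year integer year.
#' @return a lot name unique in the store.
#' @export
name_child_lot <- function(store, germplasm, location, year) {
  comp <- function(x) gsub("_", "-", trimws(as.character(x)), fixed = TRUE)
  base <- paste(comp(germplasm), comp(location), as.integer(year), sep = "_")
  existing <- store$tables$seed_lot$name
  if (!(base %in% existing)) return(base)
  n <- 2L
  while (paste0(base, "_", n) %in% existing) n <- n + 1L
  paste0(base, "_", n)
}

st_parent_multiplicity <- function(kind, n) {
  ok <- switch(kind,
    reproduction = n == 1L, selection = n == 1L, diffusion = n == 1L,
    cross = n == 2L, mixture = n >= 2L)
  if (!ok)
    st_multiplicity(sprintf(
      "a %s event takes %s parent lot(s), got %d", kind,
      switch(kind, cross = "exactly 2", mixture = "2 or more", "exactly 1"), n))
}

# Adds a relation guarding the two structural invariants that the automatic
# child creation cannot itself violate when callers wire existing lots.
st_add_relation <- function(store, parent_id, child_id, event_id, quantity_g) {
  if (parent_id == child_id)
    st_cycle("a seed lot cannot be its own parent")
  # adding parent -> child creates a cycle iff parent is reachable from child
  rel <- store$tables$relation
  frontier <- child_id
  seen <- integer(0)
  while (length(frontier)) {
    if (parent_id %in% frontier) st_cycle("relation would create a cycle")
    seen <- c(seen, frontier)
    frontier <- setdiff(rel$child_id[rel$parent_id %in% frontier], seen)
  }
  st_append(store, "relation",
            list(parent_id = parent_id, child_id = child_id,
                 event_id = event_id, quantity_g = quantity_g))
}

#' Record an event linking seed lots
#'
#' The generic entry point behind the per-kind wrappers. Parents are given by
#' lot name with the grams taken from each (\code{NA} = unknown: the relation
#' is recorded but the parent's ledger is not debited). The output lot(s) are
#' created automatically: same germplasm as the parent for reproduction,
#' selection and diffusion; a new auto-registered germplasm
#' \code{"<mother> x <father>"} for a cross and the sorted parent germplasm
#' names joined by \code{" + "} for a mixture (unless \code{germplasm_name}
#' overrides it). The child sits at the event location (diffusion: the
#' recipient location) with the event's year, and carries
#' \code{origin = FALSE}.
#'
#' @param store a \code{seedlot_store}.
#' @param kind one of [event_kinds()].
#' @param parents character vector of parent lot names. For a cross the first
#'   is the mother, the second the father.
#' @param quantities_g grams used from each parent (recycled \code{NA} when
#'   omitted).
#' @param date event date in any accepted dialect (bare year permitted).
#' @param location event location name; for a diffusion this is the recipient
#'   location.
#' @param actor optional person name.
#' @param project optional project tag.
#' @param event_label optional external identifier (file \code{event_id});
#'   defaults to \code{"ev<n>"}.
#' @param selection_labels for selection: one or more labels, each producing
#'   one derivative child lot.
#' @param germplasm_name override for the auto-derived child germplasm name
#'   (cross/mixture).
#' @param harvest_date for reproduction: harvest date; sets the child year.
#' @param harvested_g for reproduction: harvested grams, stored as the child
#'   lot's initial quantity (never credited back to the parent).
#' @param plot optional plot/block note for reproduction.
#' @param recipient for diffusion: recipient person name.
#' @return a list with \code{event} (label), \code{children} (lot names) and
#'   \code{relations} (relation ids), invisibly.
#' @export
record_event <- function(store, kind, parents, quantities_g = NA_real_, date,
                         location, actor = NULL, project = NA_character_,
                         event_label = NULL, selection_labels = NULL,
                         germplasm_name = NULL, harvest_date = NULL,
                         harvested_g = NA_real_, plot = NULL,
                         recipient = NULL) {
  kind <- match.arg(kind, st_event_kinds)
  parents <- as.character(parents)
  st_parent_multiplicity(kind, length(parents))
  q_raw <- vapply(as.numeric(quantities_g), st_check_g, numeric(1),
                  what = "quantity used")
  quantities_g <- rep_len(q_raw, length(parents))
  prow <- do.call(rbind, lapply(parents, lot_row, store = store))
  d <- parse_date(date)
  loc_id <- location_id(store, location)
  actor_id <- NA_integer_
  if (!is.null(actor) && !is.na(actor) && nzchar(actor)) {
    a <- st_row_by(store, "person", "name", actor)
    if (nrow(a) == 0L) st_unknown(sprintf("unknown person '%s'", actor))
    actor_id <- a$id
  }
  year <- as.integer(format(d$date, "%Y"))

  # child germplasm
  gt <- store$tables$germplasm
  parent_germ <- gt[match(prow$germplasm_id, gt$id), , drop = FALSE]
  child_gid <- switch(kind,
    cross = {
      nm <- if (!is.null(germplasm_name)) germplasm_name else
        paste(parent_germ$name[1], "x", parent_germ$name[2])
      register_germplasm(store, nm, parent_germ$species[1],
                         st_name_of(store, "germplasm_type",
                                    parent_germ$type_id[1], "label"))
    },
    mixture = {
      nm <- if (!is.null(germplasm_name)) germplasm_name else
        paste(sort(unique(parent_germ$name)), collapse = " + ")
      sp <- paste(unique(parent_germ$species), collapse = " / ")
      register_germplasm(store, nm, sp, "population")
    },
    parent_germ$id[1])

  extra <- switch(kind,
    reproduction = if (!is.null(plot)) paste0("plot=", plot) else NA_character_,
    selection = paste0("labels=", paste(selection_labels, collapse = ",")),
    diffusion = if (!is.null(recipient)) paste0("recipient=", recipient) else NA_character_,
    NA_character_)
  if (!is.null(event_label) &&
      any(store$tables$event$label == event_label, na.rm = TRUE))
    st_duplicate(sprintf("event id '%s' already recorded", event_label))
  eid <- st_append(store, "event",
                   list(label = if (is.null(event_label)) NA_character_ else event_label,
                        kind = kind, date = d$date, date_precision = d$precision,
                        date_text = d$text, location_id = loc_id,
                        actor_id = actor_id, project = project, extra = extra))
  if (is.null(event_label))
    store$tables$event$label[store$tables$event$id == eid] <- paste0("ev", eid)

  child_germ_name <- st_name_of(store, "germplasm", child_gid)
  child_year <- year
  child_initial <- NA_real_
  if (kind == "reproduction") {
    if (!is.null(harvest_date) && !is.na(harvest_date) && nzchar(harvest_date))
      child_year <- as.integer(format(parse_date(harvest_date)$date, "%Y"))
    child_initial <- st_check_g(harvested_g, "harvested quantity")
  }

  make_child <- function(comment = NA_character_) {
    nm <- name_child_lot(store, child_germ_name, location, child_year)
    st_append(store, "seed_lot",
              list(name = nm, germplasm_id = child_gid, location_id = loc_id,
                   year = child_year, initial_g = child_initial,
                   origin = FALSE, comment = comment))
    nm
  }

  if (kind == "selection") {
    labels <- selection_labels
    if (is.null(labels) || length(labels) < 1L)
      st_validation("a selection event needs at least one selection label")
    children <- vapply(labels, function(lb) make_child(paste0("selection:", lb)),
                       character(1))
    qsel <- rep_len(q_raw, length(labels))  # grams per selection label
    rel_ids <- vapply(seq_along(children), function(i)
      st_add_relation(store, prow$id[1], lot_row(store, children[i])$id, eid,
                      qsel[i]), integer(1))
  } else {
    children <- make_child()
    cid <- lot_row(store, children)$id
    rel_ids <- vapply(seq_along(parents), function(i)
      st_add_relation(store, prow$id[i], cid, eid, quantities_g[i]), integer(1))
  }
  invisible(list(event = store$tables$event$label[store$tables$event$id == eid],
                 children = unname(children), relations = unname(rel_ids)))
}

#' Per-kind event wrappers
#'
#' Convenience fronts over [record_event()] with the vocabulary of each event
#' kind. All return the same (event, children, relations) list, invisibly.
#'
#' @param store a \code{seedlot_store}.
#' @param sown_lot,parent,mother,father,lot,parents parent lot name(s).
#' @param date,location,actor,project,event_label see [record_event()].
#' @param quantity_sown_g,quantity_used_g,quantities_g,quantity_g grams used
#'   from the parent(s); \code{NA} = unknown (no ledger debit, a warning at
#'   import time).
#' @param harvest_date,harvested_g,plot reproduction payload; the harvested
#'   quantity becomes the child lot's initial stock.
#' @param labels selection labels; one child lot per label.
#' @param germplasm_name optional override of the derived mixture/cross
#'   germplasm name.
#' @param recipient_location,recipient_person diffusion recipient; must differ
#'   from the lot's current location or holder.
#' @name event_wrappers
NULL

#' @rdname event_wrappers
#' @export
record_reproduction <- function(store, sown_lot, date, location,
                                actor = NULL, quantity_sown_g = NA_real_,
                                harvest_date = NULL, harvested_g = NA_real_,
                                plot = NULL, project = NA_character_,
                                event_label = NULL) {
  record_event(store, "reproduction", sown_lot, quantity_sown_g, date,
               location, actor, project, event_label,
               harvest_date = harvest_date, harvested_g = harvested_g,
               plot = plot)
}

#' @rdname event_wrappers
#' @export
record_cross <- function(store, mother, father, date, location, actor = NULL,
                         quantities_g = NA_real_, germplasm_name = NULL,
                         project = NA_character_, event_label = NULL) {
  record_event(store, "cross", c(mother, father), quantities_g, date, location,
               actor, project, event_label, germplasm_name = germplasm_name)
}

#' @rdname event_wrappers
#' @export
record_selection <- function(store, parent, labels, date, location,
                             actor = NULL, quantity_used_g = NA_real_,
                             project = NA_character_, event_label = NULL) {
  record_event(store, "selection", parent, quantity_used_g, date, location,
               actor, project, event_label, selection_labels = labels)
}

#' @rdname event_wrappers
#' @export
record_mixture <- function(store, parents, date, location, actor = NULL,
                           quantities_g = NA_real_, germplasm_name = NULL,
                           project = NA_character_, event_label = NULL) {
  record_event(store, "mixture", parents, quantities_g, date, location, actor,
               project, event_label, germplasm_name = germplasm_name)
}

#' @rdname event_wrappers
#' @export
record_diffusion <- function(store, lot, recipient_location, recipient_person,
                             quantity_g = NA_real_, date, actor = NULL,
                             project = NA_character_, event_label = NULL) {
  lrow <- lot_row(store, lot)
  rl <- st_row_by(store, "location", "name", recipient_location)
  if (nrow(rl) == 0L)
    st_abort("seedtrace_unknown_recipient",
             sprintf("unknown recipient location '%s'", recipient_location))
  if (!is.null(recipient_person) && !is.na(recipient_person) && nzchar(recipient_person)) {
    if (nrow(st_row_by(store, "person", "name", recipient_person)) == 0L)
      st_abort("seedtrace_unknown_recipient",
               sprintf("unknown recipient person '%s'", recipient_person))
  } else {
    recipient_person <- NULL
  }
  same_loc <- rl$id == lrow$location_id
  same_person <- !is.null(recipient_person) && !is.null(actor) &&
    !is.na(actor) && recipient_person == actor
  if (same_loc && (is.null(recipient_person) || same_person))
    st_validation("diffusion recipient must differ from the lot's current location or holder")
  record_event(store, "diffusion", lot, quantity_g, date, recipient_location,
               actor, project, event_label, recipient = recipient_person)
}
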