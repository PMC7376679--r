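# The store is a set of relational tables (one data.frame per entity type)
# held in an environment, so all mutating operations share reference
# semantics, plus per-table id counters. It persists to a single canonical
# JSON file; see store_save()/store_load().

st_schema <- function() {
  d0 <- as.Date(character())
  list(
    germplasm_type = data.frame(id = integer(), label = character()),
    germplasm = data.frame(id = integer(), name = character(),
                           species = character(), type_id = integer()),
    location  = data.frame(id = integer(), name = character(),
                           kind = character(), region = character()),
    person    = data.frame(id = integer(), name = character(),
                           role = character(), location_id = integer()),
    variable  = data.frame(id = integer(), name = character(),
                           scope = character(), level = character()),
    method    = data.frame(id = integer(), name = character(),
                           description = character()),
    seed_lot  = data.frame(id = integer(), name = character(),
                           germplasm_id = integer(), location_id = integer(),
                           year = integer(), initial_g = numeric(),
                           origin = logical(), comment = character()),
    event     = data.frame(id = integer(), label = character(),
                           kind = character(), date = d0,
                           date_precision = character(),
                           date_text = character(), location_id = integer(),
                           actor_id = integer(), project = character(),
                           extra = character()),
    relation  = data.frame(id = integer(), parent_id = integer(),
                           child_id = integer(), event_id = integer(),
                           quantity_g = numeric()),
    raw_data  = data.frame(id = integer(), subject_type = character(),
                           subject_id = integer(), variable_id = integer(),
                           method_id = integer(), value = character(),
                           date = d0, date_precision = character(),
                           individual = integer()),
    inventory = data.frame(id = integer(), lot_id = integer(), date = d0,
                           date_precision = character(),
                           measured_g = numeric())
  )
}

#' Create an empty seed-lot store
#'
#' The store is the single handle every other operation takes: a relational
#' registry of germplasms, locations, people, seed lots, events, relations,
#' measured data and stock inventories. It is an environment, so functions
#' that record events or import files mutate it in place.
#'
#' @return an object of class \code{seedlot_store}.
#' @seealso [store_save()], [store_load()], [create_seed_lot()], [record_event()]
#' @export
store_new <- function() {
  s <- new.env(parent = emptyenv())
  s$tables <- st_schema()
  s$counters <- stats::setNames(rep(0L, length(s$tables)), names(s$tables))
  class(s) <- "seedlot_store"
  s
}

#' @export
print.seedlot_store <- function(x, ...) {
  n <- vapply(x$tables, nrow, integer(1))
  cat("<seedlot_store>\n")
  cat(sprintf("  seed lots: %d  events: %d  relations: %d\n",
              n[["seed_lot"]], n[["event"]], n[["relation"]]))
  cat(sprintf("  germplasms: %d  locations: %d  persons: %d\n",
              n[["germplasm"]], n[["location"]], n[["person"]]))
  cat(sprintf("  data points: %d  inventories: %d\n",
              n[["raw_data"]], n[["inventory"]]))
  invisible(x)
}

#' Deep-copy a store
#'
#' Used by the importer to apply a file to a scratch copy first, so a
#' rejected import leaves the original untouched.
#' @param store a \code{seedlot_store}.
#' @return an independent \code{seedlot_store} with identical contents.
#' @export
store_clone <- function(store) {
  s2 <- store_new()
  s2$tables <- store$tables
  s2$counters <- store$counters
  s2
}

# Overwrite the contents of `into` with those of `from` (commit of a clone).
st_commit <- function(into, from) {
  into$tables <- from$tables
  into$counters <- from$counters
  invisible(into)
}

# Append one row (a named list covering the schema minus id) to a table,
# assigning the next id. Returns the new id.
st_append <- function(store, table, row) {
  tbl <- store$tables[[table]]
  id <- store$counters[[table]] + 1L
  row$id <- id
  row <- row[names(tbl)]
  new <- tbl[0, , drop = FALSE]
  for (cn in names(tbl)) {
    v <- row[[cn]]
    if (is.null(v)) v <- NA
    new[1, cn] <- v
  }
  store$tables[[table]] <- rbind(tbl, new)
  store$counters[[table]] <- id
  id
}

st_round_g <- function(x) round(x * 10) / 10  # grams at 0.1 g resolution

st_check_g <- function(x, what) {
  if (is.null(x) || length(x) == 0L || is.na(x)) return(NA_real_)
  if (!is.numeric(x) || x < 0)
    st_validation(sprintf("%s must be a non-negative quantity in grams, got %s",
                          what, format(x)))
  st_round_g(as.numeric(x))
}

# --- lookups ---------------------------------------------------------------

st_row_by <- function(store, table, col, value) {
  tbl <- store$tables[[table]]
  tbl[!is.na(tbl[[col]]) & tbl[[col]] == value, , drop = FALSE]
}

lot_row <- function(store, name) {
  r <- st_row_by(store, "seed_lot", "name", name)
  if (nrow(r) == 0L) st_unknown(sprintf("unknown seed lot '%s'", name))
  r
}

lot_row_by_id <- function(store, id) {
  store$tables$seed_lot[match(id, store$tables$seed_lot$id), , drop = FALSE]
}

event_row_by_id <- function(store, id) {
  store$tables$event[match(id, store$tables$event$id), , drop = FALSE]
}

st_name_of <- function(store, table, ids, col = "name") {
  store$tables[[table]][[col]][match(ids, store$tables[[table]]$id)]
}

# --- registration ----------------------------------------------------------

# Shared idempotent-registration logic: same natural key with an identical
# payload returns the existing id; same key with a different payload is a
# duplicate-key error.
st_register <- function(store, table, key_cols, row) {
  tbl <- store$tables[[table]]
  hit <- rep(TRUE, nrow(tbl))
  for (k in key_cols) {
    v <- tbl[[k]]
    hit <- hit & !is.na(v) & v == row[[k]]
  }
  if (any(hit)) {
    old <- tbl[which(hit)[1], , drop = FALSE]
    same <- vapply(setdiff(names(row), "id"), function(cn) {
      a <- old[[cn]]; b <- row[[cn]]
      (is.na(a) && (is.null(b) || is.na(b))) || (!is.na(a) && !is.null(b) && !is.na(b) && a == b)
    }, logical(1))
    if (all(same)) return(old$id)
    st_duplicate(sprintf("%s with key (%s) already registered with a different payload",
                         table, paste(unlist(row[key_cols]), collapse = ", ")))
  }
  st_append(store, table, row)
}

st_nonempty <- function(x, what) {
  if (length(x) != 1L || is.na(x) || !nzchar(trimws(x)))
    st_validation(sprintf("%s must be a non-empty string", what))
  trimws(x)
}

#' Register reference entities
#'
#' Reference entities are identified by natural keys: everything by its name,
#' except germplasms which are unique on the (name, species) pair — the same
#' variety name under two species spellings is two distinct germplasms.
#' Re-registering an identical entity is a no-op returning the existing id;
#' the same key with a different payload raises a duplicate-key error.
#'
#' @param store a \code{seedlot_store}.
#' @param label,name natural key of the entity.
#' @param species species of the genetic material (free text; any cultivated
#'   species, or several, is acceptable).
#' @param type germplasm type label (e.g. \code{"population"},
#'   \code{"inbred line"}, \code{"hybrid"}); auto-registered.
#' @param kind location kind: one of \code{"farm"}, \code{"institute"},
#'   \code{"station"}, \code{"other"}.
#' @param region optional postal/region string.
#' @param role person role: \code{"farmer"}, \code{"facilitator"},
#'   \code{"researcher"}, \code{"other"}.
#' @param location optional location name the person is based at.
#' @param scope variable scope: \code{"phenotype"}, \code{"environment"} or
#'   \code{"practice"}.
#' @param level \code{"global"} (one value per subject) or \code{"individual"}
#'   (one value per measured individual).
#' @param description free-text description of a measurement method.
#' @return the stored integer id, invisibly usable as a foreign key.
#' @name registration
NULL

#' @rdname registration
#' @export
register_germplasm_type <- function(store, label) {
  st_register(store, "germplasm_type", "label",
              list(label = st_nonempty(label, "germplasm type label")))
}

#' @rdname registration
#' @export
register_germplasm <- function(store, name, species, type = "population") {
  name <- st_nonempty(name, "germplasm name")
  species <- st_nonempty(species, "species")
  type_id <- register_germplasm_type(store, type)
  st_register(store, "germplasm", c("name", "species"),
              list(name = name, species = species, type_id = type_id))
}

#' @rdname registration
#' @export
register_location <- function(store, name, kind = "farm", region = NA_character_) {
  kind <- match.arg(kind, c("farm", "institute", "station", "other"))
  st_register(store, "location", "name",
              list(name = st_nonempty(name, "location name"), kind = kind,
                   region = region))
}

#' @rdname registration
#' @export
register_person <- function(store, name, role = "farmer", location = NULL) {
  role <- match.arg(role, c("farmer", "facilitator", "researcher", "other"))
  loc_id <- NA_integer_
  if (!is.null(location) && !is.na(location) && nzchar(location)) {
    r <- st_row_by(store, "location", "name", location)
    if (nrow(r) == 0L) st_unknown(sprintf("unknown location '%s'", location))
    loc_id <- r$id
  }
  st_register(store, "person", "name",
              list(name = st_nonempty(name, "person name"), role = role,
                   location_id = loc_id))
}

#' @rdname registration
#' @export
register_variable <- function(store, name, scope = "phenotype", level = "global") {
  scope <- match.arg(scope, c("phenotype", "environment", "practice"))
  level <- match.arg(level, c("global", "individual"))
  st_register(store, "variable", "name",
              list(name = st_nonempty(name, "variable name"), scope = scope,
                   level = level))
}

#' @rdname registration
#' @export
register_method <- function(store, name, description = NA_character_) {
  st_register(store, "method", "name",
              list(name = st_nonempty(name, "method name"),
                   description = description))
}

# Resolve a germplasm by name (and species when given); errors when the name
# alone is ambiguous across species.
germplasm_id <- function(store, name, species = NULL) {
  g <- st_row_by(store, "germplasm", "name", name)
  if (!is.null(species) && !is.na(species))
    g <- g[g$species == species, , drop = FALSE]
  if (nrow(g) == 0L) st_unknown(sprintf("unknown germplasm '%s'", name))
  if (nrow(g) > 1L)
    st_validation(sprintf("germplasm name '%s' is ambiguous across species; give species", name))
  g$id
}

location_id <- function(store, name) {
  r <- st_row_by(store, "location", "name", name)
  if (nrow(r) == 0L) st_unknown(sprintf("unknown location '%s'", name))
  r$id
}

#' Create a seed lot
#'
#' A seed lot is the atomic traceable unit: a named quantity of seeds of one
#' germplasm, held at one location, produced or acquired in one year. Lots
#' created directly (rather than as the output of an event) carry
#' \code{origin = TRUE}, meaning their history genuinely starts here; pass
#' \code{origin = FALSE} for a lot whose earlier history exists but was not
#' recorded — generation numbers over such lots are flagged as minima.
#'
#' @param store a \code{seedlot_store}.
#' @param germplasm germplasm name (must be registered).
#' @param location stock location name (must be registered).
#' @param year creation year, 1900--2100.
#' @param initial_g initial stock in grams (0.1 g resolution), or \code{NA}
#'   when unknown. Unknown is a distinct state from 0.
#' @param name lot name; defaults to the \code{<germplasm>_<location>_<year>}
#'   pattern of [name_child_lot()].
#' @param species species, needed only to disambiguate a germplasm name used
#'   under several species.
#' @param origin whether the lot's recorded history starts at this lot.
#' @param comment optional free-text comment.
#' @return the lot name, invisibly.
#' @export
create_seed_lot <- function(store, germplasm, location, year,
                            initial_g = NA_real_, name = NULL, species = NULL,
                            origin = TRUE, comment = NA_character_) {
  gid <- germplasm_id(store, germplasm, species)
  lid <- location_id(store, location)
  year <- as.integer(year)
  if (is.na(year) || year < 1900L || year > 2100L)
    st_validation(sprintf("implausible creation year %s", year))
  initial_g <- st_check_g(initial_g, "initial quantity")
  if (is.null(name)) {
    name <- name_child_lot(store, germplasm, location, year)
  } else {
    name <- st_nonempty(name, "seed lot name")
    if (nrow(st_row_by(store, "seed_lot", "name", name)) > 0L)
      st_duplicate(sprintf("seed lot '%s' already exists", name))
  }
  st_append(store, "seed_lot",
            list(name = name, germplasm_id = gid, location_id = lid,
                 year = year, initial_g = initial_g, origin = isTRUE(origin),
                 comment = comment))
  invisible(name)
}

#' Delete an origin seed lot
#'
#' A lot can only be removed directly while no relation references it (lots
#' that are part of the graph are removed through [delete_event()]). Its
#' attached data and inventories are removed with it.
#' @param store a \code{seedlot_store}.
#' @param name lot name.
#' @return the deletion counts, invisibly.
#' @export
delete_seed_lot <- function(store, name) {
  lot <- lot_row(store, name)
  rel <- store$tables$relation
  if (any(rel$parent_id == lot$id | rel$child_id == lot$id))
    st_downstream(sprintf("seed lot '%s' is referenced by relations; delete its events instead", name))
  rd <- store$tables$raw_data
  drop_rd <- rd$subject_type == "lot" & rd$subject_id == lot$id
  store$tables$raw_data <- rd[!drop_rd, , drop = FALSE]
  inv <- store$tables$inventory
  drop_inv <- inv$lot_id == lot$id
  store$tables$inventory <- inv[!drop_inv, , drop = FALSE]
  store$tables$seed_lot <-
    store$tables$seed_lot[store$tables$seed_lot$id != lot$id, , drop = FALSE]
  invisible(list(lots_deleted = 1L, data_deleted = sum(drop_rd)))
}

# --- measured data and inventories ----------------------------------------

#' Attach a measured value to a seed lot or a relation
#'
#' Each data point is described by a variable and (optionally) a method. A
#' variable at individual level requires \code{individual}, a positive index
#' of the measured individual; global-level data must not carry one.
#'
#' @param store a \code{seedlot_store}.
#' @param lot,parent,child subject: either a lot name, or a (parent, child)
#'   lot-name pair identifying a relation.
#' @param variable variable name (registered via [register_variable()]).
#' @param value the measured value, kept as text; numeric interpretation is
#'   left to consumers.
#' @param method optional method name.
#' @param date optional measurement date (any accepted dialect).
#' @param individual individual index, iff the variable is individual-level.
#' @return the raw-data id, invisibly.
#' @export
add_raw_data <- function(store, lot = NULL, parent = NULL, child = NULL,
                         variable, value, method = NULL, date = NULL,
                         individual = NA_integer_) {
  if (!is.null(lot) && (is.null(parent) && is.null(child))) {
    subject_type <- "lot"
    subject_id <- lot_row(store, lot)$id
  } else if (is.null(lot) && !is.null(parent) && !is.null(child)) {
    subject_type <- "relation"
    pid <- lot_row(store, parent)$id
    cid <- lot_row(store, child)$id
    rel <- store$tables$relation
    hit <- rel[rel$parent_id == pid & rel$child_id == cid, , drop = FALSE]
    if (nrow(hit) == 0L)
      st_unknown(sprintf("no relation %s -> %s", parent, child))
    subject_id <- hit$id[nrow(hit)]  # newest when repeated across years
  } else {
    st_validation("exactly one subject: either `lot` or the (`parent`, `child`) pair")
  }
  vrow <- st_row_by(store, "variable", "name", variable)
  if (nrow(vrow) == 0L) st_unknown(sprintf("unknown variable '%s'", variable))
  mid <- NA_integer_
  if (!is.null(method) && !is.na(method) && nzchar(method))
    mid <- register_method(store, method)
  ind <- if (is.null(individual) || is.na(individual)) NA_integer_ else as.integer(individual)
  if (vrow$level == "individual" && (is.na(ind) || ind < 1L))
    st_validation(sprintf("variable '%s' is individual-level: a positive individual index is required", variable))
  if (vrow$level == "global" && !is.na(ind))
    st_validation(sprintf("variable '%s' is global-level: no individual index allowed", variable))
  d <- list(date = as.Date(NA), precision = NA_character_)
  if (!is.null(date) && !is.na(date) && nzchar(date)) d <- parse_date(date)
  id <- st_append(store, "raw_data",
            list(subject_type = subject_type, subject_id = subject_id,
                 variable_id = vrow$id, method_id = mid,
                 value = as.character(value), date = d$date,
                 date_precision = d$precision, individual = ind))
  invisible(id)
}

#' Record a stock inventory
#'
#' An inventory is a dated absolute measurement of a lot's remaining stock;
#' when the ledger is replayed it resets the balance to the measured value,
#' superseding everything before it.
#' @param store a \code{seedlot_store}.
#' @param lot lot name.
#' @param date inventory date.
#' @param measured_g measured remaining stock, grams.
#' @return the inventory id, invisibly.
#' @export
record_inventory <- function(store, lot, date, measured_g) {
  lrow <- lot_row(store, lot)
  g <- st_check_g(measured_g, "measured quantity")
  if (is.na(g)) st_validation("an inventory requires a measured quantity")
  d <- parse_date(date)
  id <- st_append(store, "inventory",
                  list(lot_id = lrow$id, date = d$date,
                       date_precision = d$precision, measured_g = g))
  invisible(id)
}

# --- graph integrity -------------------------------------------------------

# Kahn's algorithm over the relation edges; NULL when a cycle exists.
store_toposort <- function(store) {
  lots <- store$tables$seed_lot$id
  rel <- store$tables$relation
  indeg <- stats::setNames(integer(length(lots)), lots)
  for (cid in rel$child_id) indeg[as.character(cid)] <- indeg[as.character(cid)] + 1L
  queue <- lots[indeg[as.character(lots)] == 0L]
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    kids <- rel$child_id[rel$parent_id == v]
    for (k in kids) {
      indeg[as.character(k)] <- indeg[as.character(k)] - 1L
      if (indeg[as.character(k)] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order) != length(lots)) NULL else order
}

#' Check store integrity
#'
#' Verifies referential integrity (every foreign key resolves, every data
#' point's subject exists) and that the relation graph is a DAG.
#' @param store a \code{seedlot_store}.
#' @return \code{TRUE}, or a character vector describing each violation.
#' @export
store_check <- function(store) {
  t <- store$tables
  bad <- character(0)
  chk <- function(ids, ref, what) {
    ids <- ids[!is.na(ids)]
    miss <- setdiff(ids, ref$id)
    if (length(miss)) bad <<- c(bad, sprintf("%s: unresolved ids %s", what,
                                             paste(miss, collapse = ",")))
  }
  chk(t$germplasm$type_id, t$germplasm_type, "germplasm.type_id")
  chk(t$person$location_id, t$location, "person.location_id")
  chk(t$seed_lot$germplasm_id, t$germplasm, "seed_lot.germplasm_id")
  chk(t$seed_lot$location_id, t$location, "seed_lot.location_id")
  chk(t$event$location_id, t$location, "event.location_id")
  chk(t$event$actor_id, t$person, "event.actor_id")
  chk(t$relation$parent_id, t$seed_lot, "relation.parent_id")
  chk(t$relation$child_id, t$seed_lot, "relation.child_id")
  chk(t$relation$event_id, t$event, "relation.event_id")
  chk(t$raw_data$variable_id, t$variable, "raw_data.variable_id")
  chk(t$raw_data$method_id, t$method, "raw_data.method_id")
  chk(t$inventory$lot_id, t$seed_lot, "inventory.lot_id")
  rd <- t$raw_data
  chk(rd$subject_id[rd$subject_type == "lot"], t$seed_lot, "raw_data.subject(lot)")
  chk(rd$subject_id[rd$subject_type == "relation"], t$relation, "raw_data.subject(relation)")
  if (is.null(store_toposort(store))) bad <- c(bad, "relation graph has a cycle")
  if (length(bad)) bad else TRUE
}

# --- persistence -----------------------------------------------------------

# Canonical JSON text of the whole store: tables ordered by schema, rows by
# id, dates as ISO strings. Deterministic, so dump -> load -> dump is
# byte-identical.
#' Serialise a store to canonical JSON text
#' @param store a \code{seedlot_store}.
#' @return a single JSON string.
#' @export
store_dump <- function(store) {
  ser <- lapply(store$tables, function(tbl) {
    tbl <- tbl[order(tbl$id), , drop = FALSE]
    for (cn in names(tbl)) if (inherits(tbl[[cn]], "Date"))
      tbl[[cn]] <- format(tbl[[cn]], "%Y-%m-%d")
    tbl
  })
  as.character(jsonlite::toJSON(
    list(format = "seedtrace-store", version = 1L,
         counters = as.list(store$counters), tables = ser),
    dataframe = "columns", na = "null", digits = 10, auto_unbox = TRUE,
    pretty = TRUE))
}

#' Save / load a store as a single JSON file
#' @param store a \code{seedlot_store}.
#' @param path file path of the store.
#' @return \code{store_load} returns the reconstructed \code{seedlot_store};
#'   \code{store_save} returns \code{path} invisibly.
#' @export
store_save <- function(store, path) {
  writeLines(store_dump(store), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname store_save
#' @export
store_load <- function(path) {
  if (!file.exists(path)) st_unknown(sprintf("no store at '%s'", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!identical(raw$format, "seedtrace-store"))
    st_format(sprintf("'%s' is not a seed-lot store", path))
  store <- store_new()
  schema <- st_schema()
  for (tn in names(schema)) {
    cols <- raw$tables[[tn]]
    proto <- schema[[tn]]
    n <- if (length(cols) && length(cols[[1]])) length(cols[[1]]) else 0L
    tbl <- proto
    if (n > 0L) {
      built <- lapply(names(proto), function(cn) {
        v <- unlist(lapply(cols[[cn]], function(x) if (is.null(x)) NA else x))
        if (is.null(v)) v <- rep(NA, n)
        target <- proto[[cn]]
        if (inherits(target, "Date")) as.Date(as.character(v))
        else if (is.integer(target)) as.integer(v)
        else if (is.numeric(target)) as.numeric(v)
        else if (is.logical(target)) as.logical(v)
        else as.character(v)
      })
      names(built) <- names(proto)
      tbl <- as.data.frame(built, stringsAsFactors = FALSE)
    }
    store$tables[[tn]] <- tbl
  }
  store$counters <- stats::setNames(
    vapply(names(schema), function(tn) {
      cv <- raw$counters[[tn]]
      if (is.null(cv)) 0L else as.integer(cv)
    }, integer(1)), names(schema))
  store
}
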