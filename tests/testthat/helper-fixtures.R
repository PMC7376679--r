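# Shared fixtures (built in code) and independent oracles used across tests.

base_store <- function() {
  s <- store_new()
  for (f in c("Farm-A", "Farm-B", "Farm-C")) register_location(s, f)
  register_person(s, "Alice", "farmer", "Farm-A")
  register_person(s, "Bob", "farmer", "Farm-B")
  s
}

# Backcross worked example: A x B -> C in a first step, then C x B.
backcross_store <- function() {
  s <- base_store()
  for (g in c("A", "B")) register_germplasm(s, g, "wheat")
  create_seed_lot(s, "A", "Farm-A", 2015, 500, name = "A-lot")
  create_seed_lot(s, "B", "Farm-A", 2015, 500, name = "B-lot")
  step1 <- record_cross(s, "A-lot", "B-lot", "2016-06-01", "Farm-A",
                        germplasm_name = "C", event_label = "x1")
  step2 <- record_cross(s, step1$children[1], "B-lot", "2017-06-01", "Farm-A",
                        event_label = "x2")
  list(store = s, c_lot = step1$children[1], backcross = step2$children[1])
}

# Polycross worked example: A x B -> C, D x E -> F, then F x C.
polycross_store <- function() {
  s <- base_store()
  for (g in c("A", "B", "D", "E")) register_germplasm(s, g, "wheat")
  for (g in c("A", "B", "D", "E"))
    create_seed_lot(s, g, "Farm-A", 2015, 500, name = paste0(g, "-lot"))
  s1 <- record_cross(s, "A-lot", "B-lot", "2016-06-01", "Farm-A",
                     germplasm_name = "C", event_label = "x1")
  s2 <- record_cross(s, "D-lot", "E-lot", "2016-06-01", "Farm-A",
                     germplasm_name = "F", event_label = "x2")
  s3 <- record_cross(s, s2$children[1], s1$children[1], "2017-06-01", "Farm-A",
                     event_label = "x3")
  list(store = s, c_lot = s1$children[1], f_lot = s2$children[1],
       polycross = s3$children[1])
}

# Generation chain example: origin at Farm-A -> repro(Farm-A) -> repro(Farm-A)
# -> diffusion to Farm-B -> repro(Farm-B).
generation_chain_store <- function(origin_flag = TRUE) {
  s <- base_store()
  register_germplasm(s, "Renan", "wheat")
  create_seed_lot(s, "Renan", "Farm-A", 2015, 1000, name = "L0",
                  origin = origin_flag)
  r1 <- record_reproduction(s, "L0", "2016-04-01", "Farm-A", "Alice", 100,
                            "2016-08-01", 500, event_label = "r1")
  r2 <- record_reproduction(s, r1$children[1], "2017-04-01", "Farm-A", "Alice",
                            100, "2017-08-01", 500, event_label = "r2")
  d1 <- record_diffusion(s, r2$children[1], "Farm-B", "Bob", 200, "2017-09-01",
                         event_label = "d1")
  r3 <- record_reproduction(s, d1$children[1], "2018-04-01", "Farm-B", "Bob",
                            100, "2018-08-01", 500, event_label = "r3")
  list(store = s, tip = r3$children[1],
       chain = c("L0", r1$children[1], r2$children[1], d1$children[1],
                 r3$children[1]))
}

# Three-event deletion fixture: one reproduction whose harvest parents two
# further reproductions.
fan_store <- function() {
  s <- base_store()
  register_germplasm(s, "Renan", "wheat")
  create_seed_lot(s, "Renan", "Farm-A", 2015, 1000, name = "root")
  r1 <- record_reproduction(s, "root", "2016-04-01", "Farm-A", "Alice", 100,
                            "2016-08-01", 800, event_label = "r1")
  mid <- r1$children[1]
  record_reproduction(s, mid, "2017-04-01", "Farm-A", "Alice", 100,
                      "2017-08-01", 500, event_label = "r2")
  record_reproduction(s, mid, "2017-04-15", "Farm-A", "Alice", 100,
                      "2017-08-01", 500, event_label = "r3")
  list(store = s, mid = mid)
}

# Store with 2 lot-level, 3 relation-level and 4 individual data points.
query_fixture <- function() {
  s <- base_store()
  register_germplasm(s, "Renan", "wheat")
  register_germplasm(s, "Piave", "wheat")
  create_seed_lot(s, "Renan", "Farm-A", 2015, 1000, name = "R-lot")
  create_seed_lot(s, "Piave", "Farm-B", 2015, 1000, name = "P-lot")
  r1 <- record_reproduction(s, "R-lot", "2016-04-01", "Farm-A", "Alice", 100,
                            "2016-08-01", 500, event_label = "r1")
  r2 <- record_reproduction(s, "P-lot", "2016-04-01", "Farm-B", "Bob", 100,
                            "2016-08-01", 500, event_label = "r2")
  register_variable(s, "soil", scope = "environment")
  register_variable(s, "yield")
  register_variable(s, "height", level = "individual")
  add_raw_data(s, lot = "R-lot", variable = "soil", value = "clay")
  add_raw_data(s, lot = "P-lot", variable = "soil", value = "sand",
               date = "2016-05-01")
  add_raw_data(s, parent = "R-lot", child = r1$children[1], variable = "yield",
               value = "3.1", date = "2016-08-01")
  add_raw_data(s, parent = "P-lot", child = r2$children[1], variable = "yield",
               value = "2.7", date = "2016-08-01")
  add_raw_data(s, parent = "P-lot", child = r2$children[1], variable = "yield",
               value = "2.9", method = "combine")
  for (i in 1:4)
    add_raw_data(s, lot = r1$children[1], variable = "height",
                 value = as.character(80 + i), date = "2016-07-10",
                 individual = i)
  list(store = s, child_r = r1$children[1], child_p = r2$children[1])
}

# --- independent oracles ---------------------------------------------------

# Ancestor lot ids by raw reachability over the relation edge list (no use of
# the package's traversal code).
oracle_ancestor_ids <- function(store, lot_name) {
  rel <- store$tables$relation
  id <- store$tables$seed_lot$id[store$tables$seed_lot$name == lot_name]
  acc <- integer(0)
  frontier <- id
  while (length(frontier)) {
    ps <- unique(rel$parent_id[rel$child_id %in% frontier])
    frontier <- setdiff(ps, acc)
    acc <- union(acc, frontier)
  }
  acc
}

# Exhaustive path enumeration for generation numbers: every root-to-lot path
# is walked explicitly; total = max over paths of reproductions after the
# last cross/mixture on the path, local = max trailing run of reproductions
# at the lot's location (selection transparent, everything else breaks).
oracle_generation <- function(store, lot_name) {
  tabs <- store$tables
  lrow <- tabs$seed_lot[tabs$seed_lot$name == lot_name, ]
  rel <- tabs$relation
  ev <- tabs$event
  paths <- list()
  walk <- function(id, edges) {
    up <- rel[rel$child_id == id, , drop = FALSE]
    if (nrow(up) == 0L) {
      paths[[length(paths) + 1L]] <<- list(edges = edges, end = id)
      return(invisible())
    }
    for (i in seq_len(nrow(up)))
      walk(up$parent_id[i],
           c(edges, list(list(kind = ev$kind[ev$id == up$event_id[i]],
                              loc = ev$location_id[ev$id == up$event_id[i]]))))
  }
  walk(lrow$id, list())
  total <- 0L; local <- 0L; truncated <- FALSE
  for (p in paths) {
    # edges run child -> root; count until a cross/mixture is hit
    t <- 0L
    for (e in p$edges) {
      if (e$kind %in% c("cross", "mixture")) break
      if (e$kind == "reproduction") t <- t + 1L
    }
    l <- 0L
    for (e in p$edges) {
      if (e$kind == "reproduction" && e$loc == lrow$location_id) l <- l + 1L
      else if (e$kind == "selection" && e$loc == lrow$location_id) next
      else break
    }
    total <- max(total, t); local <- max(local, l)
    end_row <- tabs$seed_lot[tabs$seed_lot$id == p$end, ]
    if (!end_row$origin) truncated <- TRUE
  }
  list(total = total, local = local,
       quality = if (truncated) "minimum" else "exact")
}

# Closed-form stock for a lot with no inventory entries:
# initial - sum(known debits); with inventories: the last inventory value
# minus the known debits dated strictly after it (debit on the same day
# precedes the inventory under the ledger tie rule).
oracle_stock_closed_form <- function(store, lot_name) {
  tabs <- store$tables
  lrow <- tabs$seed_lot[tabs$seed_lot$name == lot_name, ]
  rel <- tabs$relation
  ev <- tabs$event
  deb <- rel[rel$parent_id == lrow$id & !is.na(rel$quantity_g), , drop = FALSE]
  deb_dates <- ev$date[match(deb$event_id, ev$id)]
  inv <- tabs$inventory[tabs$inventory$lot_id == lrow$id, , drop = FALSE]
  if (nrow(inv) == 0L) {
    if (is.na(lrow$initial_g)) return(-sum(deb$quantity_g))
    return(lrow$initial_g - sum(deb$quantity_g))
  }
  inv <- inv[order(inv$date, inv$id), , drop = FALSE]
  last <- inv[nrow(inv), ]
  last$measured_g - sum(deb$quantity_g[deb_dates > last$date])
}

# Every (parent, child, event) triple that should remain after removing the
# given events; used to check cascade deletion leaves no dangling reference.
expect_store_intact <- function(store) {
  expect_true(isTRUE(store_check(store)))
}

write_tmp_tsv <- function(lines) {
  p <- tempfile(fileext = ".tsv")
  writeLines(lines, p)
  p
}
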