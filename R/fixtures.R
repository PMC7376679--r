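# Deterministic synthetic breeding-network generator. Emulates the structure
# of a participatory network — farms holding lines of population-varieties,
# reproducing them every year, occasionally diffusing seed to another farm,
# selecting within a lot, crossing or mixing lots — purely at the level of
# lots, events and grams. No genetics or agronomy is simulated.

#' Define a synthetic network scenario
#'
#' Year 0 creates one origin lot per (farm, germplasm) pair; each following
#' year every active line is sown and its harvest becomes the line's new
#' current lot, and with the given per-lot-year probabilities the fresh
#' harvest is also diffused to another farm, selected, crossed with a lot of
#' another germplasm on the same farm, or mixed with other same-species lots
#' of the farm — each such event starting a new active line. The same seed
#' yields byte-identical output.
#'
#' @param n_farms,n_germplasms,n_years network dimensions (years of
#'   multiplication after the origin year).
#' @param p_diffusion,p_mixture,p_selection,p_cross per-lot-year event
#'   probabilities in [0, 1].
#' @param p_inventory per-lot-year probability that a stock inventory of the
#'   sown lot is recorded after sowing.
#' @param seed RNG seed.
#' @param initial_g origin lots' starting stock, grams.
#' @param sown_g grams sown at each reproduction (also the grams moved by a
#'   diffusion; selections use half of it, mixtures a quarter per parent).
#' @param harvest_mult length-2 range of the harvest multiplier: harvested
#'   grams = sown x Uniform(min, max), at 0.1 g resolution.
#' @param start_year calendar year of the origin lots.
#' @return an object of class \code{network_scenario}.
#' @export
network_scenario <- function(n_farms = 3, n_germplasms = 2, n_years = 3,
                             p_diffusion = 0, p_mixture = 0, p_selection = 0,
                             p_cross = 0, p_inventory = 0, seed = 1,
                             initial_g = 1000, sown_g = 150,
                             harvest_mult = c(3, 6), start_year = 2015) {
  sc <- list(n_farms = as.integer(n_farms),
             n_germplasms = as.integer(n_germplasms),
             n_years = as.integer(n_years),
             p_diffusion = p_diffusion, p_mixture = p_mixture,
             p_selection = p_selection, p_cross = p_cross,
             p_inventory = p_inventory,
             seed = as.integer(seed), initial_g = initial_g, sown_g = sown_g,
             harvest_mult = as.numeric(harvest_mult),
             start_year = as.integer(start_year))
  probs <- unlist(sc[c("p_diffusion", "p_mixture", "p_selection", "p_cross",
                       "p_inventory")])
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    st_validation("event probabilities must lie in [0, 1]")
  if (sc$n_farms < 1L || sc$n_germplasms < 1L || sc$n_years < 0L)
    st_validation("network dimensions must be positive (n_years may be 0)")
  if (length(sc$harvest_mult) != 2L || any(sc$harvest_mult <= 0) ||
      sc$harvest_mult[1] > sc$harvest_mult[2])
    st_validation("harvest_mult must be an increasing positive range")
  if (sc$initial_g < 0 || sc$sown_g <= 0)
    st_validation("quantities must be positive")
  structure(sc, class = "network_scenario")
}

#' Read / write a scenario as a plain key=value config file
#' @param path config file path.
#' @param scenario a \code{network_scenario}.
#' @return \code{read_scenario} returns a \code{network_scenario}.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) st_unknown(sprintf("no scenario config at '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("=", lines, fixed = TRUE) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)))
  args <- lapply(stats::setNames(vals, keys), function(v) {
    if (grepl(",", v, fixed = TRUE)) as.numeric(trimws(strsplit(v, ",")[[1]]))
    else if (grepl("^-?[0-9.]+$", v)) as.numeric(v) else v
  })
  do.call(network_scenario, args[names(args) %in% names(formals(network_scenario))])
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  lines <- vapply(names(unclass(scenario)), function(k)
    sprintf("%s = %s", k, paste(scenario[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

st_with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic seed network
#'
#' Builds the full store for a [network_scenario()] and, when \code{dir} is
#' given, also writes the corresponding tabulated files: one
#' \code{origin_lots.tsv} (origin lots are not expressible in the six event
#' formats) plus one file per (year, kind) with non-empty content, named so
#' that lexicographic order is a valid import order (later years reference
#' lots created in earlier ones). The returned manifest carries the exact
#' expected counts for oracle tests.
#'
#' @param scenario a \code{network_scenario}.
#' @param dir optional directory to write the file set into (created if
#'   needed).
#' @return list(store, manifest, files, scenario); \code{manifest} has
#'   lots_total, origin_lots, events (named count per kind), relations,
#'   grams_debited, inventories.
#' @export
generate_network <- function(scenario, dir = NULL) {
  stopifnot(inherits(scenario, "network_scenario"))
  st_with_seed(scenario$seed, {
    sc <- scenario
    store <- store_new()
    farms <- sprintf("Farm-%d", seq_len(sc$n_farms))
    germs <- sprintf("Pop-%d", seq_len(sc$n_germplasms))
    species <- "Triticum aestivum"
    for (f in farms) register_location(store, f, "farm")
    farmers <- sprintf("Farmer-%d", seq_len(sc$n_farms))
    for (i in seq_len(sc$n_farms)) register_person(store, farmers[i], "farmer", farms[i])
    for (g in germs) register_germplasm(store, g, species, "population")

    # active lines: one row per line currently multiplied somewhere
    lines <- data.frame(lot = character(), farm = character(),
                        stringsAsFactors = FALSE)
    origin_rows <- list()
    for (f in farms) for (g in germs) {
      nm <- create_seed_lot(store, g, f, sc$start_year, sc$initial_g)
      lines[nrow(lines) + 1L, ] <- list(nm, f)
      origin_rows[[length(origin_rows) + 1L]] <-
        c(name = nm, germplasm = g, species = species, type = "population",
          location = f, year = sc$start_year, initial_g = sc$initial_g)
    }

    files <- list()  # name -> character lines
    counters <- c(reproduction = 0L, cross = 0L, selection = 0L,
                  mixture = 0L, diffusion = 0L)
    n_inventories <- 0L
    next_label <- function(kind) {
      counters[kind] <<- counters[kind] + 1L
      sprintf("%s-%04d", kind, counters[kind])
    }
    add_row <- function(year_idx, kind, cells) {
      fn <- sprintf("y%02d_%d_%s.tsv", year_idx,
                    match(kind, c("reproduction", "cross", "mixture",
                                  "selection", "diffusion")), kind)
      if (is.null(files[[fn]]))
        files[[fn]] <<- st_tsv_line(st_format_table[[kind]])
      files[[fn]] <<- c(files[[fn]], st_tsv_line(cells))
    }
    germ_of <- function(lot) {
      lr <- lot_row(store, lot)
      st_name_of(store, "germplasm", lr$germplasm_id)
    }
    farmer_of <- function(farm) farmers[match(farm, farms)]

    for (y in seq_len(sc$n_years)) {
      cal <- sc$start_year + y
      sow_date <- sprintf("%d-04-15", cal)
      harvest_date <- sprintf("%d-08-01", cal)
      late_date <- sprintf("%d-09-15", cal)
      snapshot <- lines  # lines entering this year
      new_lines <- lines[0, ]
      # 1. every active line is reproduced; the harvest replaces the line's lot
      for (i in seq_len(nrow(snapshot))) {
        sown <- snapshot$lot[i]; farm <- snapshot$farm[i]
        mult <- stats::runif(1, sc$harvest_mult[1], sc$harvest_mult[2])
        harvested <- st_round_g(sc$sown_g * mult)
        lab <- next_label("reproduction")
        res <- record_reproduction(store, sown, sow_date, farm,
                                   farmer_of(farm), sc$sown_g, harvest_date,
                                   harvested, event_label = lab)
        add_row(y, "reproduction",
                c(lab, sown, sow_date, farm, farmer_of(farm), sc$sown_g,
                  harvest_date, harvested))
        new_lines[nrow(new_lines) + 1L, ] <- list(res$children[1], farm)
        if (stats::runif(1) < sc$p_inventory) {
          left <- current_stock(store, sown)$grams
          if (!is.na(left) && left > 0) {
            record_inventory(store, sown, sprintf("%d-05-01", cal),
                             st_round_g(left * stats::runif(1, 0.8, 1)))
            n_inventories <- n_inventories + 1L
          }
        }
      }
      lines <- new_lines
      fresh <- lines  # harvests of this year; stochastic events act on these
      # Plan the stochastic events per lot (RNG draws in lot order), then
      # record them grouped by kind in the same order the files are
      # re-imported, so auto-generated child names coincide in both stores.
      plans <- list(cross = list(), mixture = list(), selection = list(),
                    diffusion = list())
      for (i in seq_len(nrow(fresh))) {
        lot <- fresh$lot[i]; farm <- fresh$farm[i]
        if (sc$n_farms > 1L && stats::runif(1) < sc$p_diffusion) {
          others <- setdiff(farms, farm)
          other <- others[sample.int(length(others), 1L)]
          plans$diffusion[[length(plans$diffusion) + 1L]] <-
            list(lot = lot, other = other)
        }
        if (stats::runif(1) < sc$p_selection)
          plans$selection[[length(plans$selection) + 1L]] <-
            list(lot = lot, farm = farm)
        if (stats::runif(1) < sc$p_cross) {
          mates <- fresh$lot[fresh$farm == farm & fresh$lot != lot]
          mates <- mates[vapply(mates, germ_of, character(1)) != germ_of(lot)]
          if (length(mates)) {
            father <- mates[sample.int(length(mates), 1L)]
            plans$cross[[length(plans$cross) + 1L]] <-
              list(lot = lot, father = father, farm = farm)
          }
        }
        if (stats::runif(1) < sc$p_mixture) {
          mates <- fresh$lot[fresh$farm == farm & fresh$lot != lot]
          if (length(mates)) {
            k <- sample.int(min(3L, length(mates)), 1L)
            plans$mixture[[length(plans$mixture) + 1L]] <-
              list(comp = c(lot, mates[seq_len(k)]), farm = farm)
          }
        }
      }
      for (p in plans$cross) {
        lab <- next_label("cross")
        # the cross format carries no quantity column: grams used stay unknown
        res <- record_cross(store, p$lot, p$father, late_date, p$farm,
                            farmer_of(p$farm), event_label = lab)
        add_row(y, "cross",
                c(lab, p$lot, p$father, late_date, p$farm, farmer_of(p$farm)))
        lines[nrow(lines) + 1L, ] <- list(res$children[1], p$farm)
      }
      for (p in plans$mixture) {
        lab <- next_label("mixture")
        q <- st_round_g(sc$sown_g / 4)
        res <- record_mixture(store, p$comp, late_date, p$farm,
                              farmer_of(p$farm),
                              quantities_g = rep(q, length(p$comp)),
                              event_label = lab)
        for (pl in p$comp)
          add_row(y, "mixture", c(lab, pl, q, late_date, p$farm,
                                  farmer_of(p$farm)))
        lines[nrow(lines) + 1L, ] <- list(res$children[1], p$farm)
      }
      for (p in plans$selection) {
        lab <- next_label("selection")
        q <- st_round_g(sc$sown_g / 2)
        res <- record_selection(store, p$lot, "sel-1", late_date, p$farm,
                                farmer_of(p$farm), q, event_label = lab)
        add_row(y, "selection",
                c(lab, p$lot, "sel-1", late_date, p$farm, farmer_of(p$farm), q))
        lines[nrow(lines) + 1L, ] <- list(res$children[1], p$farm)
      }
      for (p in plans$diffusion) {
        lab <- next_label("diffusion")
        res <- record_diffusion(store, p$lot, p$other, farmer_of(p$other),
                                sc$sown_g, late_date, event_label = lab)
        add_row(y, "diffusion",
                c(lab, p$lot, p$other, farmer_of(p$other), sc$sown_g, late_date))
        lines[nrow(lines) + 1L, ] <- list(res$children[1], p$other)
      }
    }

    rel <- store$tables$relation
    manifest <- list(
      lots_total = nrow(store$tables$seed_lot),
      origin_lots = sum(store$tables$seed_lot$origin),
      events = as.list(vapply(st_event_kinds, function(k)
        sum(store$tables$event$kind == k), integer(1))),
      relations = nrow(rel),
      grams_debited = st_round_g(sum(rel$quantity_g, na.rm = TRUE)),
      inventories = n_inventories)

    written <- character(0)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      ol <- c(st_tsv_line(c("name", "germplasm", "species", "type", "location",
                            "year", "initial_g")),
              vapply(origin_rows, st_tsv_line, character(1)))
      writeLines(ol, file.path(dir, "origin_lots.tsv"), useBytes = TRUE)
      written <- "origin_lots.tsv"
      for (fn in sort(names(files))) {
        writeLines(files[[fn]], file.path(dir, fn), useBytes = TRUE)
        written <- c(written, fn)
      }
    }
    list(store = store, manifest = manifest, files = written,
         scenario = scenario)
  })
}

#' Import the origin-lot registration file of a generated fixture
#'
#' Origin lots enter the system without a parent event, so they are not
#' expressible in the six event formats; this companion format registers the
#' germplasms and locations and creates the lots with their recorded names.
#' @param store a \code{seedlot_store}.
#' @param path path of \code{origin_lots.tsv}.
#' @return number of lots created, invisibly.
#' @export
import_origin_lots <- function(store, path) {
  tsv <- st_read_tsv(path)
  need <- c("name", "germplasm", "species", "type", "location", "year", "initial_g")
  if (length(setdiff(need, tsv$header)))
    st_format("origin_lots.tsv: missing mandatory headers")
  n <- 0L
  for (r in tsv$rows) {
    v <- stats::setNames(r$cells[match(need, tsv$header)], need)
    register_location(store, v[["location"]])
    register_germplasm(store, v[["germplasm"]], v[["species"]], v[["type"]])
    create_seed_lot(store, v[["germplasm"]], v[["location"]],
                    as.integer(v[["year"]]),
                    as.numeric(v[["initial_g"]]), name = v[["name"]],
                    species = v[["species"]])
    n <- n + 1L
  }
  invisible(n)
}

#' Re-import a generated fixture directory into a store
#'
#' Imports \code{origin_lots.tsv} then every event file in lexicographic
#' (= dependency) order. Any rejected file aborts with its report.
#' @param store a \code{seedlot_store}.
#' @param dir directory written by [generate_network()].
#' @return list of \code{import_report}s, invisibly.
#' @export
import_fixture_dir <- function(store, dir) {
  ol <- file.path(dir, "origin_lots.tsv")
  if (file.exists(ol)) import_origin_lots(store, ol)
  fns <- sort(setdiff(list.files(dir, pattern = "\\.tsv$"), "origin_lots.tsv"))
  reports <- list()
  for (fn in fns) {
    kind <- sub("^y\\d+_\\d+_(.*)\\.tsv$", "\\1", fn)
    rep <- import_file(store, kind, path = file.path(dir, fn))
    if (rep$status != "ok")
      st_validation(sprintf("fixture file '%s' rejected: %s", fn,
                            paste(report_lines(rep), collapse = " | ")))
    reports[[fn]] <- rep
  }
  invisible(reports)
}
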