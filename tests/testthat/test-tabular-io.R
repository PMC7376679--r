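repro_header <- paste(c("event_id", "sown_seed_lot", "sowing_date", "location",
                        "actor", "quantity_sown_g", "harvest_date",
                        "quantity_harvested_g"), collapse = "\t")

repro_row <- function(id, lot, extra = character(0)) {
  paste(c(id, lot, "2016-04-01", "Farm-A", "Alice", "150", "2016-08-01", "600",
          extra), collapse = "\t")
}

two_lot_store <- function() {
  s <- base_store()
  register_germplasm(s, "Renan", "wheat")
  create_seed_lot(s, "Renan", "Farm-A", 2015, 1000, name = "lotA")
  create_seed_lot(s, "Renan", "Farm-A", 2015, 1000, name = "lotB")
  s
}

test_that("parse_date accepts exactly the three dialects, day-first for slashes", {
  expect_equal(parse_date("2016-08-01")$date, as.Date("2016-08-01"))
  expect_equal(parse_date("01/08/2016")$date, as.Date("2016-08-01"))
  expect_identical(parse_date("2016")$precision, "year")
  expect_equal(parse_date("2016")$date, as.Date("2016-07-01"))
  expect_error(parse_date("13/13/2016"), class = "seedtrace_date_parse")
  expect_error(parse_date("2016-13-01"), class = "seedtrace_date_parse")
  expect_error(parse_date("31/02/2016"), class = "seedtrace_date_parse")
  expect_error(parse_date("Aug 1 2016"), class = "seedtrace_date_parse")
  expect_error(parse_date(""), class = "seedtrace_date_parse")
  # property: the two full dialects agree on random valid dates
  set.seed(1)
  days <- as.Date("1995-01-01") + sample.int(12000, 40)
  for (d in format(days, "%Y-%m-%d")) {
    slash <- format(as.Date(d), "%d/%m/%Y")
    expect_equal(parse_date(slash)$date, parse_date(d)$date)
  }
})

test_that("a valid reproduction file imports atomically with correct counts", {
  s <- two_lot_store()
  rep <- import_file(s, "reproduction",
                     text = c(repro_header, repro_row("r1", "lotA"),
                              repro_row("r2", "lotB")))
  expect_identical(rep$status, "ok")
  expect_identical(rep$events_created, 2L)
  expect_identical(rep$lots_created, 2L)
  expect_identical(nrow(s$tables$event), 2L)
  # harvested child initial quantity comes from the file
  child <- children(s, "lotA")$lot[1]
  expect_equal(s$tables$seed_lot$initial_g[s$tables$seed_lot$name == child], 600)
  expect_equal(current_stock(s, "lotA")$grams, 850)
})

test_that("one unknown sown lot rejects the whole file and mutates nothing", {
  s <- two_lot_store()
  before <- store_dump(s)
  rep <- import_file(s, "reproduction",
                     text = c(repro_header, repro_row("r1", "lotA"),
                              repro_row("r2", "ghost")))
  expect_identical(rep$status, "rejected")
  expect_identical(rep$events_created, 0L)
  err <- rep$issues[rep$issues$severity == "error", ]
  expect_identical(err$row, 3L)
  expect_identical(store_dump(s), before)
})

test_that("extra columns are variable columns creating one data point per non-empty cell", {
  s <- two_lot_store()
  rep <- import_file(s, "reproduction",
                     text = c(paste(repro_header, "awn_color", sep = "\t"),
                              repro_row("r1", "lotA", "white"),
                              repro_row("r2", "lotB", "")))
  expect_identical(rep$status, "ok")
  expect_identical(rep$data_points_created, 1L)
  expect_true(any(grepl("awn_color", rep$issues$message)))  # auto-registration warning
  expect_identical(nrow(st <- s$tables$raw_data), 1L)
  expect_identical(st$subject_type, "relation")
})

test_that("the variable-header micro-syntax routes method, date and harvest target", {
  s <- two_lot_store()
  hdr <- paste(repro_header, "protein:NIRS@2016-09-15", "tkw#harvest",
               sep = "\t")
  rep <- import_file(s, "reproduction",
                     text = c(hdr, paste(repro_row("r1", "lotA"),
                                         "11.8", "48.2", sep = "\t")))
  expect_identical(rep$status, "ok")
  expect_identical(rep$data_points_created, 2L)
  rd <- s$tables$raw_data
  vr <- s$tables$variable
  protein <- rd[rd$variable_id == vr$id[vr$name == "protein"], ]
  expect_identical(protein$subject_type, "relation")
  expect_equal(protein$date, as.Date("2016-09-15"))
  expect_identical(s$tables$method$name, "NIRS")
  tkw <- rd[rd$variable_id == vr$id[vr$name == "tkw"], ]
  expect_identical(tkw$subject_type, "lot")
  child <- children(s, "lotA")$lot[1]
  expect_identical(s$tables$seed_lot$name[s$tables$seed_lot$id == tkw$subject_id],
                   child)
})

test_that("duplicate event ids: error within a file, warning + skip on re-import", {
  s <- two_lot_store()
  rep <- import_file(s, "reproduction",
                     text = c(repro_header, repro_row("r1", "lotA"),
                              repro_row("r1", "lotB")))
  expect_identical(rep$status, "rejected")
  ok <- import_file(s, "reproduction", text = c(repro_header, repro_row("r1", "lotA")))
  expect_identical(ok$status, "ok")
  again <- import_file(s, "reproduction",
                       text = c(repro_header, repro_row("r1", "lotA")))
  expect_identical(again$status, "ok")
  expect_identical(again$events_created, 0L)
  expect_true(any(again$issues$severity == "warning"))
  expect_identical(nrow(s$tables$event), 1L)
})

test_that("a missing mandatory header is a format error, not a rejected report", {
  s <- two_lot_store()
  expect_error(import_file(s, "reproduction",
                           text = c("event_id\tsown_seed_lot", "r1\tlotA")),
               class = "seedtrace_format")
  expect_error(import_file(s, "nonsense", text = "x"),
               class = "seedtrace_format")
})

test_that("header remapping lets a site dialect import unchanged", {
  s <- two_lot_store()
  dialect <- sub("sown_seed_lot", "lot_seme", repro_header)
  rep <- import_file(s, "reproduction",
                     text = c(dialect, repro_row("r1", "lotA")),
                     header_map = c(lot_seme = "sown_seed_lot"))
  expect_identical(rep$status, "ok")
})

test_that("export_template prefills one row per lot and empty selections are refused", {
  s <- two_lot_store()
  tpl <- export_template(s, c("lotA", "lotB", "lotA"), "reproduction")
  expect_length(tpl, 4L)
  cells <- strsplit(tpl[2], "\t")[[1]]
  expect_identical(cells[2], "lotA")   # sown_seed_lot prefilled
  expect_identical(cells[4], "Farm-A") # location prefilled
  expect_identical(cells[3], "")       # sowing date left to the user
  expect_error(export_template(s, character(0), "reproduction"),
               class = "seedtrace_incompatible_selection")
})

test_that("filled templates import one event per row; untouched re-import is a detected duplicate", {
  s <- two_lot_store()
  tpl <- export_template(s, c("lotA", "lotB"), "reproduction")
  fill <- function(line) {
    c <- strsplit(line, "\t")[[1]]
    length(c) <- 8; c[is.na(c)] <- ""
    c[3] <- "2016-04-01"; c[6] <- "100"; c[7] <- "2016-08-01"; c[8] <- "500"
    paste(c, collapse = "\t")
  }
  rep <- import_file(s, "reproduction", text = c(tpl[1], vapply(tpl[-1], fill, "")))
  expect_identical(rep$status, "ok")
  expect_identical(rep$events_created, 2L)
  # untouched template now re-imports as duplicates: detectable no-op
  again <- import_file(s, "reproduction", text = tpl)
  expect_identical(again$status, "ok")
  expect_identical(again$events_created, 0L)
  expect_identical(sum(again$issues$severity == "warning"), 2L)
})

test_that("a reproduction file drives alone/cascade deletion atomically", {
  fx <- fan_store()
  del <- c("event_id\tsown_seed_lot\tsowing_date\tlocation\tactor\tquantity_sown_g\tharvest_date\tquantity_harvested_g",
           "r1\troot\t\t\t\t\t\t")
  rep <- delete_from_file(fx$store, text = del, cascade = TRUE)
  expect_identical(rep$events_deleted, 3L)
  expect_store_intact(fx$store)

  fx2 <- fan_store()
  leaf <- sub("r1", "r2", del[2])
  rep2 <- delete_from_file(fx2$store, text = c(del[1], leaf), cascade = FALSE)
  expect_identical(rep2$events_deleted, 1L)

  fx3 <- fan_store()
  before <- store_dump(fx3$store)
  expect_error(delete_from_file(fx3$store,
                                text = c(del[1], del[2], sub("r1", "never", del[2])),
                                cascade = TRUE),
               class = "seedtrace_unknown")
  expect_identical(store_dump(fx3$store), before)
})

test_that("individual measures attach per-individual data to subject lots", {
  s <- two_lot_store()
  txt <- c("subject_seed_lot\tindividual_index\tdate\theight:ruler\tawns",
           "lotA\t1\t2016-07-01\t92.5\tpresent",
           "lotA\t2\t2016-07-01\t88.1\t",
           "lotB\t1\t\t90.0\tabsent")
  rep <- import_file(s, "individual_measures", text = txt)
  expect_identical(rep$status, "ok")
  expect_identical(rep$data_points_created, 5L)
  vr <- s$tables$variable
  expect_setequal(vr$level[vr$name %in% c("height", "awns")], "individual")
  bad <- import_file(s, "individual_measures",
                     text = c(txt[1], "lotA\t0\t\t1\t"))
  expect_identical(bad$status, "rejected")
})
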