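test_that("query_data splits data into exactly three tables with fixture counts 2/3/4", {
  fx <- query_fixture()
  res <- query_data(fx$store)
  expect_named(res, c("seed_lot_table", "relation_table", "individual_table"))
  expect_identical(nrow(res$seed_lot_table), 2L)
  expect_identical(nrow(res$relation_table), 3L)
  expect_identical(nrow(res$individual_table), 4L)
  # empty store: three empty tables
  empty <- query_data(store_new())
  expect_identical(vapply(empty, nrow, integer(1), USE.NAMES = FALSE),
                   c(0L, 0L, 0L))
})

test_that("filters are conjunctive and strengthening them only shrinks tables", {
  fx <- query_fixture()
  all <- query_data(fx$store)
  f1 <- query_data(fx$store, species = "wheat")
  f2 <- query_data(fx$store, species = "wheat", location = "Farm-B")
  for (tn in names(all)) {
    expect_lte(nrow(f1[[tn]]), nrow(all[[tn]]))
    expect_lte(nrow(f2[[tn]]), nrow(f1[[tn]]))
  }
  expect_identical(nrow(f2$relation_table), 2L)
  expect_identical(nrow(query_data(fx$store, variable = "soil")$seed_lot_table), 2L)
  expect_identical(nrow(query_data(fx$store, actor = "Bob")$relation_table), 2L)
})

test_that("date filtering uses the measure date, falling back to the event date", {
  fx <- query_fixture()
  # the undated relation measure (method combine) falls back to the r2 event
  # (sowing) date in April, so the August window catches only the dated ones
  res <- query_data(fx$store, date_range = c("2016-08-01", "2016-08-31"))
  expect_identical(nrow(res$relation_table), 2L)
  res_all <- query_data(fx$store, date_range = c("2016-04-01", "2016-08-31"))
  expect_identical(nrow(res_all$relation_table), 3L)
  res2 <- query_data(fx$store, date_range = c("2016-05-01", "2016-05-02"))
  expect_identical(nrow(res2$seed_lot_table), 1L)
  none <- query_data(fx$store, date_range = c("1999-01-01", "1999-12-31"))
  expect_identical(vapply(none, nrow, integer(1), USE.NAMES = FALSE),
                   c(0L, 0L, 0L))
  expect_error(query_data(fx$store, date_range = c("2017-01-01", "2016-01-01")),
               class = "seedtrace_validation")
})

test_that("the seed-lot card has four consistent sections", {
  fx <- query_fixture()
  card <- seed_lot_card(fx$store, "R-lot")
  expect_named(card[c("identity", "history", "data", "stock")],
               c("identity", "history", "data", "stock"))
  expect_identical(card$identity$value[card$identity$field == "germplasm"], "Renan")
  expect_true("used by" %in% card$history$role)
  expect_identical(nrow(card$data), 1L)
  expect_equal(card$stock$current$grams, current_stock(fx$store, "R-lot")$grams)
  # a harvested lot lists its creating event
  card2 <- seed_lot_card(fx$store, fx$child_r)
  expect_true("created by" %in% card2$history$role)
  expect_identical(card2$history$event[card2$history$role == "created by"], "r1")
  # an origin lot with no data still renders all four sections
  bx <- backcross_store()
  card3 <- seed_lot_card(bx$store, "A-lot")
  expect_identical(card3$history$role[1], "used by")
})

test_that("card stock equals the ledger for every lot of a generated network", {
  st <- generate_network(network_scenario(n_farms = 2, n_germplasms = 2,
                                          n_years = 2, p_diffusion = 0.4,
                                          p_inventory = 0.3, seed = 5))$store
  for (nm in st$tables$seed_lot$name) {
    card <- seed_lot_card(st, nm)
    expect_identical(card$stock$current, current_stock(st, nm))
  }
})

test_that("the relation card has two sections and lists repeated relations newest first", {
  fx <- query_fixture()
  card <- relation_card(fx$store, "P-lot", fx$child_p)
  expect_named(card, c("info", "data"))
  expect_identical(nrow(card$data), 2L)
  expect_error(relation_card(fx$store, "R-lot", fx$child_p),
               class = "seedtrace_unknown")
  card_export(card, file.path(tempdir(), "rc"))
  expect_true(file.exists(file.path(tempdir(), "rc_info.tsv")))
})

test_that("search ranks exact before prefix before substring and narrows monotonically", {
  fx <- query_fixture()
  s <- fx$store
  hits <- search_store(s, "ren")
  expect_true(all(startsWith(tolower(hits$name), "ren") | grepl("ren", tolower(hits$name))))
  expect_true("Renan" %in% hits$name)
  exact <- search_store(s, "r-lot")
  expect_identical(exact$name[1], "R-lot")
  expect_identical(exact$rank[1], 1L)
  # relations are searchable
  expect_true(any(search_store(s, "R-lot -> ")$type == "relation"))
  # extension property
  h1 <- search_store(s, "P")
  h2 <- search_store(s, "P-")
  expect_true(all(h2$name %in% h1$name))
  expect_identical(nrow(search_store(s, "zzz")), 0L)
  expect_error(search_store(s, ""), class = "seedtrace_validation")
})
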