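# The reference case: initial 1000 g, debit 300 g (2016-08-01), inventory
# 600 g (2016-12-01), debit 100 g (2017-03-01).
ledger_case <- function() {
  s <- base_store()
  register_germplasm(s, "Renan", "wheat")
  create_seed_lot(s, "Renan", "Farm-A", 2015, 1000, name = "L")
  record_reproduction(s, "L", "2016-08-01", "Farm-A", quantity_sown_g = 300,
                      event_label = "r1")
  record_inventory(s, "L", "2016-12-01", 600)
  record_reproduction(s, "L", "2017-03-01", "Farm-A", quantity_sown_g = 100,
                      event_label = "r2")
  s
}

test_that("a lot with only an initial credit has a single full-balance entry", {
  s <- base_store()
  register_germplasm(s, "Renan", "wheat")
  create_seed_lot(s, "Renan", "Farm-A", 2015, 1000, name = "L")
  h <- stock_history(s, "L")
  expect_identical(nrow(h), 1L)
  expect_identical(h$kind, "initial")
  expect_equal(h$balance_after_g, 1000)
  expect_length(attr(h, "warnings"), 0L)
})

test_that("replay applies initial, debits and inventory resets in date order", {
  s <- ledger_case()
  h <- stock_history(s, "L")
  expect_identical(h$kind, c("initial", "debit", "inventory", "debit"))
  expect_equal(h$balance_after_g, c(1000, 700, 600, 500))
  expect_equal(current_stock(s, "L")$grams, 500)
  expect_equal(current_stock(s, "L", as_of = "2016-12-15")$grams, 600)
  expect_true(is.na(current_stock(s, "L", as_of = "2014-01-01")$grams))
})

test_that("unknown initial stock replays from zero with warnings, never clamped", {
  s <- base_store()
  register_germplasm(s, "Renan", "wheat")
  create_seed_lot(s, "Renan", "Farm-A", 2015, name = "L")
  record_reproduction(s, "L", "2016-04-01", "Farm-A", quantity_sown_g = 200,
                      event_label = "r1")
  st <- current_stock(s, "L")
  expect_equal(st$grams, -200)
  expect_true(all(c("unknown_initial", "negative_balance") %in% st$warnings))
  # no entries at all: unknown, distinct from 0
  create_seed_lot(s, "Renan", "Farm-A", 2016, name = "M")
  expect_true(is.na(current_stock(s, "M")$grams))
})

test_that("history is determined by dates, not insertion order", {
  build <- function(order) {
    s <- base_store()
    register_germplasm(s, "Renan", "wheat")
    create_seed_lot(s, "Renan", "Farm-A", 2015, 1000, name = "L")
    steps <- list(
      a = function() record_reproduction(s, "L", "2016-08-01", "Farm-A",
                                         quantity_sown_g = 300, event_label = "ra"),
      b = function() record_inventory(s, "L", "2016-12-01", 600),
      c = function() record_reproduction(s, "L", "2017-03-01", "Farm-A",
                                         quantity_sown_g = 100, event_label = "rc"))
    for (k in order) steps[[k]]()
    stock_history(s, "L")
  }
  h1 <- build(c("a", "b", "c"))
  h2 <- build(c("c", "a", "b"))
  h3 <- build(c("b", "c", "a"))
  expect_equal(h1$balance_after_g, h2$balance_after_g)
  expect_equal(h1$balance_after_g, h3$balance_after_g)
  expect_identical(h1$kind, h2$kind)
})

test_that("same-date ties order initial < debit < inventory", {
  s <- base_store()
  register_germplasm(s, "Renan", "wheat")
  create_seed_lot(s, "Renan", "Farm-A", 2016, 1000, name = "L")
  # sowing and inventory on the same day: the inventory reflects post-sowing
  record_reproduction(s, "L", "2016-08-01", "Farm-A", quantity_sown_g = 300,
                      event_label = "r1")
  record_inventory(s, "L", "2016-08-01", 650)
  h <- stock_history(s, "L")
  expect_identical(h$kind[2:3], c("debit", "inventory"))
  expect_equal(current_stock(s, "L")$grams, 650)
})

test_that("closed form equals replay without inventories; inventories dominate otherwise", {
  for (seed in 0:14) {
    sc <- network_scenario(n_farms = 2, n_germplasms = 1, n_years = 3,
                           p_diffusion = 0.4, p_selection = 0.3,
                           p_inventory = if (seed %% 2) 0.5 else 0,
                           seed = seed)
    st <- generate_network(sc)$store
    for (nm in st$tables$seed_lot$name) {
      got <- current_stock(st, nm)$grams
      if (is.na(got)) next
      expect_equal(got, oracle_stock_closed_form(st, nm),
                   label = sprintf("seed %d lot %s", seed, nm))
    }
  }
})

test_that("stock history exports as TSV", {
  s <- ledger_case()
  p <- tempfile(fileext = ".tsv")
  write_tsv(stock_history(s, "L"), p)
  back <- utils::read.delim(p)
  expect_identical(names(back),
                   c("date", "kind", "amount_g", "balance_after_g", "source"))
  expect_equal(back$balance_after_g, c(1000, 700, 600, 500))
})
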