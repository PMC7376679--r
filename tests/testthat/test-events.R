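test_that("parent multiplicity is enforced per event kind", {
  s <- base_store()
  register_germplasm(s, "A", "wheat"); register_germplasm(s, "B", "wheat")
  create_seed_lot(s, "A", "Farm-A", 2015, name = "A-lot")
  create_seed_lot(s, "B", "Farm-A", 2015, name = "B-lot")
  expect_error(record_event(s, "cross", "A-lot", date = "2016", location = "Farm-A"),
               class = "seedtrace_multiplicity")
  expect_error(record_event(s, "mixture", "A-lot", date = "2016", location = "Farm-A"),
               class = "seedtrace_multiplicity")
  expect_error(record_event(s, "reproduction", c("A-lot", "B-lot"),
                            date = "2016", location = "Farm-A"),
               class = "seedtrace_multiplicity")
  expect_error(record_reproduction(s, "ghost", "2016", "Farm-A"),
               class = "seedtrace_unknown")
})

test_that("a cross derives the child germplasm '<mother> x <father>' and composes into a backcross", {
  s <- base_store()
  register_germplasm(s, "A", "wheat"); register_germplasm(s, "B", "wheat")
  create_seed_lot(s, "A", "Farm-A", 2015, name = "A-lot")
  create_seed_lot(s, "B", "Farm-A", 2015, name = "B-lot")
  st1 <- record_cross(s, "A-lot", "B-lot", "2016-06-01", "Farm-A")
  g <- s$tables$germplasm
  lot <- s$tables$seed_lot[s$tables$seed_lot$name == st1$children[1], ]
  expect_identical(g$name[g$id == lot$germplasm_id], "A x B")
  expect_false(lot$origin)
  st2 <- record_cross(s, st1$children[1], "B-lot", "2017-06-01", "Farm-A")
  expect_setequal(parents(s, st2$children[1])$lot, c(st1$children[1], "B-lot"))
  expect_store_intact(s)
})

test_that("a three-event polycross yields the full brute-force ancestor set", {
  fx <- polycross_store()
  anc <- ancestors(fx$store, fx$polycross)
  expect_setequal(anc$lots,
                  sort(with(fx$store$tables,
                            seed_lot$name[seed_lot$id %in%
                              oracle_ancestor_ids(fx$store, fx$polycross)])))
  expect_setequal(anc$lots, c("A-lot", "B-lot", "D-lot", "E-lot",
                              fx$c_lot, fx$f_lot))
  # conservation of structure: one relation per parent in each event
  expect_identical(nrow(fx$store$tables$relation), 6L)
  expect_store_intact(fx$store)
})

test_that("a mixture of four lots makes one child with a derived germplasm name", {
  s <- base_store()
  for (g in c("A", "B", "C", "D")) {
    register_germplasm(s, g, "wheat")
    create_seed_lot(s, g, "Farm-A", 2015, 400, name = paste0(g, "-lot"))
  }
  res <- record_mixture(s, c("B-lot", "D-lot", "A-lot", "C-lot"),
                        "2016-07-01", "Farm-A",
                        quantities_g = c(50, 50, 50, 50))
  expect_length(res$children, 1L)
  expect_length(res$relations, 4L)
  lot <- s$tables$seed_lot[s$tables$seed_lot$name == res$children[1], ]
  g <- s$tables$germplasm
  expect_identical(g$name[g$id == lot$germplasm_id], "A + B + C + D")
  expect_setequal(parents(s, res$children[1])$lot,
                  c("A-lot", "B-lot", "C-lot", "D-lot"))
})

test_that("a selection with k labels creates k child lots under one event", {
  s <- base_store()
  register_germplasm(s, "Renan", "wheat")
  create_seed_lot(s, "Renan", "Farm-A", 2015, 900, name = "P")
  res <- record_selection(s, "P", c("spike-1", "spike-2", "spike-3"),
                          "2016-07-15", "Farm-A", quantity_used_g = c(10, 20, 30))
  expect_length(res$children, 3L)
  expect_identical(nrow(s$tables$event), 1L)
  expect_identical(nrow(s$tables$relation), 3L)
  expect_equal(current_stock(s, "P")$grams, 900 - 60)
  # every auto-created lot has origin FALSE and a parent relation
  for (ch in res$children) {
    expect_false(s$tables$seed_lot$origin[s$tables$seed_lot$name == ch])
    expect_identical(nrow(parents(s, ch)), 1L)
  }
})

test_that("child lot naming is deterministic, collision-suffixed and escapes separators", {
  s <- store_new()
  register_location(s, "Le_Moulon", kind = "institute")
  register_germplasm(s, "Rouge_de_Bordeaux", "wheat")
  expect_identical(name_child_lot(s, "Rouge_de_Bordeaux", "Le_Moulon", 2016),
                   "Rouge-de-Bordeaux_Le-Moulon_2016")
  expect_identical(name_child_lot(s, "Rouge_de_Bordeaux", "Le_Moulon", 2016),
                   name_child_lot(s, "Rouge_de_Bordeaux", "Le_Moulon", 2016))
  create_seed_lot(s, "Rouge_de_Bordeaux", "Le_Moulon", 2016)
  expect_identical(name_child_lot(s, "Rouge_de_Bordeaux", "Le_Moulon", 2016),
                   "Rouge-de-Bordeaux_Le-Moulon_2016_2")
})

test_that("diffusion moves seed to the recipient and debits the parent ledger", {
  s <- base_store()
  register_germplasm(s, "Renan", "wheat")
  create_seed_lot(s, "Renan", "Farm-A", 2015, 1000, name = "Renan_Farm-A_2015")
  res <- record_diffusion(s, "Renan_Farm-A_2015", "Farm-B", "Bob", 200, "2016-03-01")
  expect_match(res$children[1], "^Renan_Farm-B_2016")
  expect_equal(current_stock(s, "Renan_Farm-A_2015")$grams, 800)
  # unknown quantity: child created, no debit, approximate warning
  res2 <- record_diffusion(s, "Renan_Farm-A_2015", "Farm-C", NULL,
                           NA, "2016-03-02")
  expect_length(res2$children, 1L)
  st <- current_stock(s, "Renan_Farm-A_2015")
  expect_equal(st$grams, 800)
  expect_true("approximate" %in% st$warnings)
  # recipient must differ from the current location/holder
  expect_error(record_diffusion(s, "Renan_Farm-A_2015", "Farm-A", NULL,
                                50, "2016-03-03"),
               class = "seedtrace_validation")
  expect_error(record_diffusion(s, "Renan_Farm-A_2015", "Nowhere", NULL,
                                50, "2016-03-03"),
               class = "seedtrace_unknown_recipient")
})

test_that("duplicate event labels are rejected and the DAG invariant survives mutations", {
  fx <- generation_chain_store()
  expect_error(record_reproduction(fx$store, "L0", "2019", "Farm-A",
                                   event_label = "r1"),
               class = "seedtrace_duplicate_key")
  expect_store_intact(fx$store)
})
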