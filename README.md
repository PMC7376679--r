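# seedtrace

Traceability of seed lots in decentralised, participatory plant breeding
networks.

In such networks, farmers, facilitators and researchers multiply
population-varieties on many farms over many years: a lot is sown and
re-harvested, selected within, crossed, blended with others, or handed to
another farm. Answering "where does this seed come from, how many
generations has it been multiplied here, and how much of it is left?"
requires keeping the full history. `seedtrace` keeps that history as a
typed provenance graph and makes it queryable from R or from a shell.

## The model

* **Seed lot** — a named quantity of seeds of one germplasm at one location
  in one year; the atomic traceable unit. Germplasms are identified by the
  (name, species) pair; any cultivated species (or several) is accepted.
* **Relation** — a directed parent → child link between two lots, carrying
  the grams used from the parent. Relations always belong to an **event**
  of one of five kinds: *reproduction*, *cross*, *selection*, *mixture*,
  *diffusion*. The graph is a DAG at all times; arbitrary cross designs are
  expressed step by step (backcross: `A x B -> C`, then `C x B`; polycross:
  `A x B -> C`, `D x E -> F`, then `F x C`; open pollination
  `A x B x C x D` as a mixture).
* **Stock ledger** — per lot, current stock is replayed from the initial
  quantity, every relation debit, and dated inventory measurements that
  reset the balance. Grams only, 0.1 g resolution; *unknown* is distinct
  from zero and negative balances stay visible.
* **Generation number** — total: reproductions along the deepest ancestry
  path since the nearest cross/mixture (which reset the count) or origin;
  local: the trailing run of reproductions at the lot's own location
  (broken by diffusion); flagged `minimum` when recorded history is
  truncated.
* **Files** — six tab-separated formats (five event kinds + individual
  measures) with mandatory headers and free variable columns
  (`name[:method][@date]`, `#harvest` to target the harvested lot). Import
  is two-phase and atomic: a file with any error changes nothing and the
  report lists every issue. Templates can be exported pre-filled, and a
  reproduction file can drive alone/cascade deletion of recorded events.
* **Queries** — filtered data retrieval in three tables (seed-lot data,
  relation data, individual data), a four-section seed-lot card, a
  two-section relation card, and auto-complete search.

## Worked example

```r
library(seedtrace)
s <- store_new()
register_location(s, "Farm-A"); register_location(s, "Farm-B")
register_person(s, "Alice", "farmer", "Farm-A")
register_germplasm(s, "Rouge de Bordeaux", "Triticum aestivum")
create_seed_lot(s, "Rouge de Bordeaux", "Farm-A", 2015, initial_g = 1000)

r <- record_reproduction(s, "Rouge de Bordeaux_Farm-A_2015", "2016-04-01",
                         "Farm-A", "Alice", quantity_sown_g = 300,
                         harvest_date = "2016-08-01", harvested_g = 1450,
                         event_label = "repro-1")
d <- record_diffusion(s, r$children[1], "Farm-B", NULL, 200, "2016-09-15",
                      event_label = "diff-1")

generation(s, d$children[1])
#> generation: total 1, local 0 (exact)
```

One multiplication generation separates the diffused lot from its origin
(`total 1`), but it has never been reproduced at Farm-B yet (`local 0`),
and its history is complete (`exact`). The harvested lot's ledger shows the
1450 g harvest credited as its initial stock and the 200 g diffusion
debited:

```r
stock_history(s, r$children[1])
#> stock history of Rouge de Bordeaux_Farm-A_2016 (2 entries)
#>        date    kind amount_g balance_after_g                            source
#>  2016-04-01 initial     1450            1450 lot:Rouge de Bordeaux_Farm-A_2016
#>  2016-09-15   debit      200            1250                  diffusion:diff-1
```

`seed_lot_card(s, "Rouge de Bordeaux_Farm-A_2015")` aggregates the same
store into identity / history / data / stock sections (700 g remain after
the 300 g sowing). Bulk workflows go through files instead:
`import_file()`, `export_template()`, `delete_from_file()` — see the
vignette in `vignettes/seed-lot-traceability.Rmd`.

A command-line front end wraps the same functions:

```sh
Rscript inst/exec/seedtrace init --store net.json
Rscript inst/exec/seedtrace import reproduction harvest2016.tsv --store net.json
Rscript inst/exec/seedtrace stock "Rouge de Bordeaux_Farm-A_2015" --store net.json
```

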