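---
title: "Tracing seed lots through a decentralised breeding network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing seed lots through a decentralised breeding network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedtrace)
```

## The data model

Participatory plant breeding moves seed between many farms over many years.
The atomic traceable unit is the **seed lot**: a named quantity of seeds of
one germplasm, held at one location, produced or acquired in one year.
Lots are connected by directed **relations** (parent lot → child lot, with
the grams taken from the parent), and every relation belongs to exactly one
**event** of one of five kinds:

* **reproduction** — a lot is sown and a new lot of the same germplasm is
  harvested (one on-farm generation); exactly one parent.
* **cross** — controlled mating of two parents; the child gets a new
  germplasm named `"<mother> x <father>"`. Anything more elaborate is
  described step by step: a backcross is one cross followed by a second
  cross back onto a parent lot, a polycross is a chain of pairwise crosses.
* **selection** — one or more derivative lots (one per selection label)
  extracted from a single parent.
* **mixture** — two or more lots blended into one new lot; also the way an
  open pollination among several parents is represented. The child's
  germplasm name is derived from the sorted parent germplasm names joined
  by `" + "` — a mixture is a new genetic entity.
* **diffusion** — seed handed to another actor/location; the child lot sits
  at the recipient location with the parent's germplasm.

The relation graph is a DAG by construction (output lots are always newly
created, and direct relation insertion re-checks reachability), and every
mutation preserves referential integrity — `store_check()` verifies both.
Measured values (**raw data**) attach to either a lot or a relation and are
described by a *variable* (phenotype / environment / practice, at global or
individual level) and optionally a *method*. Everything lives in a
relational registry persisted as a single canonical JSON file whose
dump → load → re-dump cycle is byte-identical.

Identity is by natural keys, as in the data files practitioners exchange:
lots, locations, people, variables and methods by name; germplasms by the
(name, species) pair, so the same variety name under two species spellings
is two distinct germplasms. Species is free text: the registry is meant to
hold any cultivated species, or several at once.

## Quantities and the stock ledger

All quantities are grams at 0.1 g resolution. *Unknown* is a distinct state
from zero: a lot with unrecorded initial stock must not claim a stock of
0 g. A lot's stock is reconstructed by replaying a totally ordered ledger:

1. an *initial* credit (the lot's starting quantity, dated at its creating
   event, or July 1 of its creation year for origin lots),
2. a *debit* for every relation using the lot as parent with known grams,
3. an *inventory* — a dated absolute measurement that resets the balance to
   the measured value, superseding everything before it.

Same-date ties order `initial < debit < inventory`: an inventory taken the
day of a sowing reflects post-sowing reality. Negative balances are kept
visible with a warning, never clamped — they are how data-entry errors
surface. Relations with unknown grams contribute no debit but mark the
history *approximate*. Harvests never credit the parent; the harvested
grams become the *child's* initial quantity.

```{r ledger}
s <- store_new()
register_location(s, "Farm-A")
register_germplasm(s, "Renan", "Triticum aestivum")
create_seed_lot(s, "Renan", "Farm-A", 2015, initial_g = 1000, name = "L")
record_reproduction(s, "L", "2016-08-01", "Farm-A", quantity_sown_g = 300,
                    event_label = "r1")
record_inventory(s, "L", "2016-12-01", 600)
record_reproduction(s, "L", "2017-03-01", "Farm-A", quantity_sown_g = 100,
                    event_label = "r2")
stock_history(s, "L")
```

## Generation numbers

The pedigree query reports, per lot, a total and a local generation number
plus a quality flag. The underlying notion — how many multiplication
generations a lot is away from where its germplasm came into being — admits
several formalisations; the one implemented here is deliberately explicit
and kept behind a single function so an alternate rule is swappable:

* **total** = over all ancestry paths, the maximum number of *reproduction*
  events since the nearest cross or mixture (which create a new germplasm
  and reset the count to zero) or since the origin lot;
* **local** = the length of the maximal trailing run of reproductions
  performed at the lot's own stock location; a diffusion breaks the run;
* **selection events count for neither** — extracting spikes from a lot is
  not a multiplication generation — and a selection at the same location is
  transparent to the local run. This resolution of an open modelling choice
  is flagged here for users who count selection cycles differently;
* **quality** is `"exact"` unless some ancestry path ends in a lot whose
  recorded history is truncated (created with `origin = FALSE` and no
  parents), in which case the numbers are lower bounds and quality is
  `"minimum"` — missing history is the only uncertainty the registry can
  represent.

The test suite cross-checks `generation()` against an exhaustive
enumeration of all root-to-lot paths on every generated network it uses
(kept under 50 lots so the enumeration stays an independent, brute-force
oracle).

## Files: the transfer medium

Bulk data enters and leaves as tab-separated UTF-8 text — robust offline on
any device. Six formats exist: one per event kind plus one for individual
measures. The header names are a documented house dialect fixed in
`format_specs()` (sites using other column names remap them via the
`header_map` of `app_config()`/`import_file()`). Beyond the mandatory
headers, any extra column is a *variable column* whose header follows
`name[:method][@date]`, with `#harvest` after the name to attach the value
to the harvested/child lot instead of the relation. An empty cell always
means *missing*, never zero.

Dates are ISO 8601 (`YYYY-MM-DD`), day-first `DD/MM/YYYY`, or a bare year;
anything else — including month-first forms — is rejected rather than
guessed. Year-only dates are normalised to July 1 for ordering while the
original precision is kept for display. A missing event date defaults to
the parent lot's creation year, with a warning: files from farms are
frequently incomplete, and a year-precision event is more useful than a
rejected row.

Import is **two-phase and atomic**: the file is validated row by row
against a scratch copy of the store so the report lists *all* problems at
once, and the real store is touched only when no error remains. Unknown
parent lots, malformed dates or quantities, wrong multiplicities and
in-file duplicate event ids are errors; unknown quantities, auto-registered
variables/locations and re-imports of already recorded event ids (skipped)
are warnings. `export_template()` closes the loop: it pre-fills a file for
selected lots (deterministic event ids included), the user completes the
remaining cells, and re-submitting an untouched template is detected as a
duplicate no-op. A reproduction file can also drive deletion
(`delete_from_file()`), alone or in cascade — cascade removes the event,
its output lots, every downstream event and lot reachable from them, and
all attached data, leaving the store referentially intact.

## The synthetic network generator

`generate_network()` produces test networks with known ground truth: year 0
creates one origin lot per (farm, germplasm); every later year each active
line is sown and its harvest becomes the line's current lot; with
configurable per-lot-year probabilities the fresh harvest is also diffused
to a uniformly chosen other farm, selected, crossed with a different
germplasm on the same farm, or mixed with 2–4 same-species lots of the
farm — each starting a new active line. Harvested grams are sown grams
times a uniform multiplier. Defaults (1000 g origin lots, 150 g sowings,
multiplier 3–6, origin year 2015) are plausible magnitudes for small-grain
on-farm multiplication plots; tests use 2–3 farms, 1–2 germplasms and 2–3
years so that brute-force oracles stay exhaustive within seconds.

The generator emulates network *structure and accounting* only: no
genetics, phenotypic values, germination loss or agronomy. Passing tests
therefore demonstrate that lineage, ledger and file round-trips are
computed correctly — not that any biological model fits real data. Real
networks also contain missing and inconsistent records; the importer's
warning machinery is exercised with explicitly corrupted files instead.

The same seed yields byte-identical stores and files (the generator
restores the caller's RNG state). Emitted files are named so lexicographic
order is a valid import order; origin lots, which no event format can
express, travel in a companion `origin_lots.tsv`. Within a year the
generator records stochastic events grouped by kind in file order, so the
automatic child names assigned on re-import coincide with the generated
store's.

## Numerical and design choices

* Grams are rounded half-up to 0.1 g at every entry point; ledger balances
  are re-rounded after each step so replay never accumulates drift.
* `parse_date()` re-validates calendar components after parsing, because
  `as.Date()` silently rolls some invalid dates on some platforms.
* Name collisions for auto-created lots are resolved by a deterministic
  `_2`, `_3`, … suffix; underscores inside name components are mapped to
  `-` so the `<germplasm>_<location>_<year>` pattern stays parseable.
* The store is held in memory and persisted to one canonical JSON file;
  at the few-thousand-lot scale of a breeding network this comfortably
  outperforms the convenience of a database server it deliberately avoids.
* Deleting an origin lot directly requires it to be relation-free; lots in
  the graph are only removed through their events.
* The CLI (`cli_main()`, `inst/exec/seedtrace`) is a pure façade: every
  subcommand is a library call plus store open/save, with exit codes
  0 / 1 (rejected or domain error) / 2 (usage).

## Limitations

Only grams are supported (no seed counts or monetary value); inventories
are absolute measurements, never additions; authorization, web rendering
and multi-user concerns are out of scope — the store is single-writer.
Generation semantics are one defensible rule among several; sites that
count selection cycles or define locality differently should wrap
`generation()` rather than reinterpret its output.
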