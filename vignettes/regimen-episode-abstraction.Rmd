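---
title: "Abstracting regimen-level chemotherapy episodes from OMOP drug exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abstracting regimen-level chemotherapy episodes from OMOP drug exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoepisodes)
```

## The abstraction problem

OMOP-CDM databases store chemotherapy as single ingredient-level
`DRUG_EXPOSURE` rows. Research questions are posed at the level of the
regimen — a named protocol such as FOLFOX (fluorouracil + leucovorin +
oxaliplatin, one cycle every 14 days) — and of the treatment course:
how many cycles a patient completed and in which treatment line. This
package abstracts the former into the latter and emits the result in
the OMOP oncology-extension `EPISODE`/`EPISODE_EVENT` shape, so that
downstream analyses can treat a chemotherapy course as a first-class
clinical object.

## The regimen knowledge base

Every regimen is described declaratively by drug roles and time
windows, serialized as a JSON document
(`{"regimens": [...], "evaluation_order": [...]}`, snake_case keys,
ISO-8601 dates):

| field | meaning | unit / default |
|---|---|---|
| `index_drugs` | dispense anchors day 1 of a candidate cycle | ingredient concept IDs |
| `combination_drugs` | all must appear inside the cycle window | ingredient concept IDs |
| `exclusion_drugs` | any appearance inside the window vetoes the match | ingredient concept IDs |
| `cycle_window_days` | component search span and maximum start-gap within one episode | protocol cycle length + 7-day grace |
| `line_window_days` | maximum start-gap before the line advances | 120 days |
| `min_cycle_gap_days` | index dispenses closer than this merge into one administration event | 5 days |

The two derived conventions deserve justification:

* **Cycle window = cycle length + 7.** Real-world courses are delayed
  by toxicity and scheduling; a one-week grace keeps a delayed cycle
  inside its episode without bridging genuinely separate courses.
  Published regimen documents state that such windows exist but not
  their values, so the fixture values are this package's own, and they
  are stored per regimen in the KB rather than hard-coded.
* **`min_cycle_gap_days` = 5.** Multi-day dispensing of one
  administration (e.g. an infusion recorded on two consecutive days)
  must not open two cycles. Five days is well below any real cycle
  length in the library yet above plausible dispensing noise. The CMF
  fixture raises it to 10 so the classic day-1 + day-8 methotrexate
  schedule forms a single cycle.

Role assignment resolves regimen ambiguity: when regimen A's drug set
is contained in regimen B's, A must list B's extra drugs as
exclusions, otherwise every B course also matches A and only
evaluation order decides. `validate_regimen_library()` flags exactly
this situation; the built-in 19-regimen library is constructed to
produce zero such diagnostics.

## The matching algorithm

Per person and per regimen, in library evaluation order:

1. **Index dates.** Distinct start dates of index-drug exposures,
   ascending, with dates closer than `min_cycle_gap_days` to the
   previously retained date merged into it (earlier date wins).
2. **Cycle match.** For each index date, the cycle window is
   `[index, index + W_cycle - 1]`, *truncated at the next index date*.
   The cycle matches iff unclaimed exposures starting in the window
   cover at least one index drug and every combination drug, and no
   exclusion-drug exposure (claimed or not) starts in the window.
3. **Episode dates.** Cycle start = the index-drug start; cycle end =
   the latest component end.
4. **Collapse and lines.** Per (person, regimen), chronological cycles
   whose successive start gaps stay within `W_cycle` form one
   treatment episode, cycles numbered 1..k; a larger gap starts a new
   episode and resets numbering. Lines start at 1 and advance on a
   regimen change (always, even after a single cycle) or a start gap
   beyond the previous regimen's `W_line`.

Design choices made where the design was genuinely open:

* **Window truncation at the next index date.** With a q14d schedule
  and a 21-day window, an untruncated window would swallow the next
  cycle's records into the current cycle and halve the cycle count.
  The grace part of the window is therefore only effective when the
  next cycle is actually late — which is exactly what it is for.
* **Greedy claiming across regimens.** A record claimed as a component
  by an earlier-evaluated regimen cannot be an index or combination
  component later; one administration never counts toward two
  regimens. Exclusion testing deliberately ignores claiming: an
  exclusion expresses "this drug was co-administered", which remains
  true whoever claimed the record.
* **Default evaluation order: most-specific first** (descending
  |index ∪ combination|, ties by ascending concept ID), so a general
  regimen cannot consume its superset regimen's records before the
  superset is tried.
* **Collapse direction.** Verbal descriptions of gap-based collapsing
  are easy to state ambiguously; this package fixes the definition:
  cycles collapse into one episode when the gap does *not* exceed the
  cycle window, and a larger gap splits episodes.
* **Day granularity.** All rules operate on exposure start dates
  (`*_date` columns); datetime precision adds nothing at cycle scale.
  Window arithmetic is day-inclusive.

The engine contains no randomness and fixed sort keys everywhere;
re-running extraction, or permuting input rows, reproduces the output
files byte for byte. Unmatched index dates (combination drug missing,
or an exclusion present) are dropped from the output but counted per
regimen in the run summary.

## The synthetic cohort generator

No public gold-standard chemotherapy EHR exists, so validation runs
against simulated cohorts whose truth is known by construction. The
generator emulates:

* per-patient courses laid out on the KB's per-cycle schedule
  templates (the same templates document each regimen, so generator
  and matcher share one source of truth), with uniform whole-cycle
  delays up to `schedule_jitter_days`;
* a configurable regimen mix, optional second-line course via a
  successor map, and optional surgery 30–90 days before chemotherapy;
* weekly ANC measurement series around a patient-level baseline
  (defaults from published cancer-cohort characteristics: mean 5582,
  SD 4403 cells/µL for a colorectal population; 3750/3199 breast;
  6517/5283 lung), with a post-cycle nadir dip at a configurable day
  and depth; nadirs below 0.5 × 10⁹/L are grade-4 events and are
  recorded in the truth together with optional fever diagnoses and
  G-CSF exposures;
* combination-drug dropout (`inject_noise()`): per affected cycle one
  combination record is removed, making the cycle unmatchable — the
  designed failure mode for sensitivity analyses.

Randomness uses one root seed with per-patient substreams, so growing
`n_patients` appends patients without reshuffling earlier ones.
Baseline ANC draws are truncated at 1500 cells/µL so background
measurements never cross event thresholds by themselves; consequently
detected events are exactly the injected ones and truth-vs-pipeline
comparisons are exact in the noise-free setting.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: dose reductions and partial
administrations, route/dose records, regimen switches mid-cycle,
vocabulary mapping noise (simulated exposures are already
ingredient-level), missing or duplicated records other than the
designed dropout, and care interruptions not expressible as schedule
jitter. Real-data performance therefore still requires chart review;
the simulator validates the algorithmic machinery, not source-data
quality.

## Neutropenia analytics

Detection scans ANC measurements (normalized to 10⁹ cells/L; values
in cells/µL are divided by 1000, recognized by the unit string or a
value > 100): grade-4 chemotherapy-induced neutropenia is ANC
< 0.5 × 10⁹/L; febrile neutropenia is ANC < 1.0 × 10⁹/L with a
same-day fever/infection diagnosis or a G-CSF exposure within 3 days
after the measurement. Measurements dated inside any chemotherapy
administration span are ignored, because the count can be transiently
depressed on the administration day itself.

Onset timing keeps, per patient, the first qualifying event within 30
days of the first first-line chemotherapy start and bins gaps into
7-day segments [2,8], [9,15], [16,22], [23,29] (weekly measurement
cadence makes finer dates spurious); gaps of 0–1 days are treated as
administration-proximal and excluded. Per-cycle incidence divides
patients with ≥ 1 event in a cycle's interval
`[cycle start, next cycle start)` by patients reaching that cycle —
the at-risk denominator, chosen over all-patients because later cycles
are reached by progressively fewer patients.

Reporting utilities enforce small-cell suppression (heat-map cells
below 10 patients masked; trajectory nodes below the configured
minimum removed with their edges, paths truncated at the configured
depth, percentages within depth).

## Validation metrics

`validation_metrics()` compares predicted (regimen, cycle count)
against a gold standard per person, stratified by predicted regimen:
PPV = regimen-matched / evaluable; cycle-count accuracy, MAE and RMSE
among regimen-matched persons; persons without gold information are
excluded from denominators and reported separately. RMSE ≥ MAE holds
by construction and is property-tested.

## Problem sizes and numerical choices

The shipped test-suite exercises: oracle equivalence of the engine
against an independent brute-force day-by-day matcher on 240
randomized small instances (≤ 5 persons, ≤ 3 regimens, ≤ 60
exposures); exact ground-truth recovery on a 500-patient mixed cohort
with second lines and surgery; dropout sensitivity at 60–80 patients
per rate with a 3-standard-deviation binomial tolerance; and exact
onset-bin recovery on a 200-patient cohort with deterministic injected
nadirs. These sizes give stable statistics while keeping the default
suite fast.

Degenerate inputs are defined rather than rejected wherever possible:
empty cohorts produce header-only tables; persons without index-drug
exposures yield no cycles; measurement rows with missing values are
ignored; a regimen definition with an empty combination set matches on
the index drug alone (monotherapy).

## Known limitations

* Matching is presence-based within windows; dose, route and
  administration completeness are out of scope.
* Regimens absent from the knowledge base are invisible; coverage is
  bounded by the KB, and the fixture library's 19 regimens are a
  curated stand-in for a production vocabulary-keyed KB.
* A drug concept mapping to multiple ingredients (combination
  products) is rejected rather than resolved.
* Treatment-line numbering considers chemotherapy episodes only;
  radiation or surgery between courses does not advance the line
  (they appear in trajectories instead).
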