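# chemoepisodes

Regimen-level chemotherapy episode abstraction for OMOP-CDM data.

## The problem

Observational health databases (EHR, claims) record chemotherapy as
ingredient-level drug exposures — one row per dispense of oxaliplatin,
fluorouracil, leucovorin, ... — while clinical research needs treatment
at the unit of the **regimen**: which protocol a patient received, how
many cycles, and in which treatment line. `chemoepisodes` closes that
gap for data standardized to the OMOP Common Data Model (v5.3): it
abstracts drug exposure records into cycle, treatment-episode and
treatment-line records in the shape of the OMOP oncology-extension
`EPISODE` / `EPISODE_EVENT` tables, and runs the downstream analyses
that regimen-level data enables (treatment patterns and trajectories,
timing of chemotherapy-induced neutropenia, validation metrics).

It is aimed at observational-research data engineers and oncology
informaticians working with OMOP-shaped sources.

## The method

Each regimen is parameterized in a JSON knowledge base as drug roles
plus time windows:

* **index drug** — its dispense date defines day 1 of a candidate
  cycle (e.g. oxaliplatin for FOLFOX);
* **combination drugs** — must all be dispensed inside the cycle
  window `[index, index + W_cycle - 1]` (fluorouracil, leucovorin);
* **exclusion drugs** — veto the match inside the window and
  distinguish a regimen from its superset (bevacizumab separates
  FOLFOX from FOLFOX + bevacizumab);
* **windows** — `W_cycle` (protocol cycle length + grace) bounds both
  the component search and the start-date gap between consecutive
  cycles of one episode; `W_line` bounds the gap before a new
  treatment line.

The matching engine evaluates regimens sequentially, most specific
first; matched records are claimed and cannot serve a later regimen.
Matched cycles with start gaps within `W_cycle` collapse into one
treatment episode (cycles numbered 1..k); lines advance on a regimen
change or a start gap beyond `W_line`. The engine is fully
deterministic: shuffling input rows or re-running produces
byte-identical output.

A built-in fixture library covers 19 common colorectal, breast and
lung cancer regimens (FOLFOX, FOLFIRI, FULV, CapeOx, AC, FEC, FAC,
CMF, platinum doublets, monotherapies, ...), each with a per-cycle
schedule template shared with the cohort simulator. The simulator
generates OMOP-shaped cohorts with known ground truth — regimen
courses with schedule jitter and combination-drug dropout, surgery
procedures, weekly ANC series with post-cycle nadirs, fever diagnoses
and G-CSF exposures — so every pipeline stage can be validated against
known answers.

## Worked example

One patient on adjuvant FOLFOX, 12 cycles every 14 days:

```r
library(chemoepisodes)
library(tibble)
lib <- builtin_regimen_library()

starts <- as.Date("2012-03-01") + seq(0, 154, by = 14)
ing <- chemo_ingredients()
exposures <- dplyr::bind_rows(
  tibble(ingredient = ing[["oxaliplatin"]],  start = starts, end = starts),
  tibble(ingredient = ing[["leucovorin"]],   start = starts, end = starts),
  tibble(ingredient = ing[["fluorouracil"]], start = starts, end = starts + 1))
exposures <- tibble(
  record_id = seq_len(nrow(exposures)), person_id = 1L,
  drug_concept_id = exposures$ingredient,
  ingredient_concept_id = exposures$ingredient,
  start_date = exposures$start, end_date = exposures$end)

result <- extract_episodes(cdm_bundle(exposures), lib)
result$episodes[1:4, c("episode_id", "episode_concept_id",
                       "episode_start_date", "episode_end_date")]
#> # A tibble: 4 × 4
#>   episode_id episode_concept_id episode_start_date episode_end_date
#>        <int>              <int> <date>             <date>
#> 1          1              32531 2012-03-01         2012-08-03
#> 2          2              32532 2012-03-01         2012-03-02
#> 3          3              32532 2012-03-15         2012-03-16
#> 4          4              32532 2012-03-29         2012-03-30
```

Row 1 is the collapsed treatment episode (concept 32531, "Treatment
Regimen"): the full course from 2012-03-01 to 2012-08-03, line 1. The
following rows are its 12 cycle episodes (concept 32532, "Treatment
Cycle"), numbered 1..12, each spanning the two fluorouracil days. The
run summary confirms `n_treatment_episodes = 1`, `n_cycles = 12`; the
12 unmatched index dates it also reports are the FOLFOX + bevacizumab
definition probing the same oxaliplatin dispenses first and (rightly)
failing for lack of bevacizumab.

Validating extraction against simulated ground truth:

```r
reg <- chemo_regimens()
spec <- cohort_spec(n_patients = 100,
  regimen_mix = setNames(c(0.6, 0.4), reg[c("FOLFOX", "FULV")]),
  second_line_probability = 0.3, seed = 42)
cohort <- generate_cohort(spec)
result <- extract_episodes(cohort$bundle, builtin_regimen_library())
predicted <- dplyr::slice_min(dplyr::group_by(result$treatments, person_id),
                              start_date, n = 1)[
  , c("person_id", "regimen_concept_id", "n_cycles")]
gold <- cohort$truth$courses[cohort$truth$courses$course_index == 1,
  c("person_id", "regimen_concept_id", "n_cycles")]
validation_metrics(predicted, gold)
#>   regimen_concept_id n_evaluable n_regimen_matched ppv cycle_accuracy mae rmse
#> 1               2001          58                58 100            100   0    0
#> 2               2003          42                42 100            100   0    0
#> 3                 NA         100               100 100            100   0    0
```

On a noise-free cohort the positive predictive value (PPV) and
cycle-count accuracy are 100% and the cycle-count mean absolute error
(MAE) / root mean square error (RMSE) are 0 — the engine recovers the
generator's truth exactly.

A command-line wrapper over the same functions ships in
`inst/scripts/chemoepisodes.R` with subcommands `validate-kb`,
`simulate`, `extract`, `analyze` and `validate`.

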