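# Shared builders for engine and analytics tests. All fixtures are
# constructed in code; day numbers count from a fixed anchor date.

anchor_date <- as.Date("2012-03-01")

day <- function(n) anchor_date + n

# One block of exposure rows for a single ingredient.
exposure_rows <- function(person, ingredient, start_days,
                          duration_days = 1L) {
  starts <- day(start_days)
  tibble::tibble(
    person_id = as.integer(person),
    drug_concept_id = as.integer(ingredient),
    ingredient_concept_id = as.integer(ingredient),
    start_date = starts,
    end_date = starts + duration_days - 1L)
}

# Assemble exposure blocks and assign record IDs.
make_exposures <- function(...) {
  df <- dplyr::bind_rows(...)
  df$record_id <- seq_len(nrow(df))
  df[, c("record_id", "person_id", "drug_concept_id",
         "ingredient_concept_id", "start_date", "end_date")]
}

# Lay out a full course for a regimen of the built-in library following
# its schedule template: cycle starts every cycle_length_days from
# `from_day`, `n_cycles` cycles.
course_rows <- function(person, regimen_name, from_day, n_cycles,
                        lib = builtin_regimen_library()) {
  def <- lib$definitions[[as.character(chemo_regimens()[[regimen_name]])]]
  sch <- def$schedule
  out <- list()
  for (c in seq_len(n_cycles)) {
    cstart <- from_day + (c - 1L) * sch$cycle_length_days
    for (cmp in sch$components) {
      out[[length(out) + 1L]] <- exposure_rows(
        person, cmp$ingredient_concept_id, cstart + cmp$day_offsets,
        cmp$duration_days)
    }
  }
  dplyr::bind_rows(out)
}

# Minimal FOLFOX-style exposures for one person: index oxaliplatin +
# leucovorin day 1, fluorouracil days 1-2, every 14 days.
folfox_person <- function(person = 1L, n_cycles = 12L, from_day = 0L) {
  make_exposures(course_rows(person, "FOLFOX", from_day, n_cycles))
}

# A tiny two-regimen library with distinct windows, for tests that need
# full control over the definitions.
toy_library <- function() {
  regimen_library(list(
    regimen_definition(901L, "toyAB", index_drugs = 11L,
                       combination_drugs = 12L,
                       exclusion_drugs = 19L,
                       cycle_window_days = 10L, line_window_days = 60L),
    regimen_definition(902L, "toyA", index_drugs = 11L,
                       exclusion_drugs = c(12L, 19L),
                       cycle_window_days = 10L, line_window_days = 60L)))
}
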