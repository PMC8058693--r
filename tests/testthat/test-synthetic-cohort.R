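reg <- chemo_regimens()

test_that("an empty cohort yields empty tables and truth", {
  spec <- cohort_spec(n_patients = 0, seed = 1)
  co <- generate_cohort(spec)
  expect_equal(nrow(co$bundle$drug_exposure), 0L)
  expect_equal(nrow(co$truth$patients), 0L)
  expect_equal(nrow(co$truth$events), 0L)
})

test_that("generation is seed-deterministic and patients use substreams", {
  mix <- setNames(c(0.5, 0.5), reg[c("FOLFOX", "AC")])
  spec <- cohort_spec(n_patients = 8, regimen_mix = mix,
                      schedule_jitter_days = 3,
                      second_line_probability = 0.5,
                      anc_model = anc_model(), seed = 11)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1$bundle$drug_exposure, co2$bundle$drug_exposure)
  expect_identical(co1$bundle$measurement, co2$bundle$measurement)
  expect_identical(co1$truth, co2$truth)

  # growing the cohort appends patients without reshuffling earlier ones
  bigger <- generate_cohort(cohort_spec(
    n_patients = 12, regimen_mix = mix, schedule_jitter_days = 3,
    second_line_probability = 0.5, anc_model = anc_model(), seed = 11))
  first8 <- bigger$bundle$drug_exposure[
    bigger$bundle$drug_exposure$person_id <= 8, ]
  expect_identical(first8, co1$bundle$drug_exposure)
})

test_that("unknown regimens in the mix are fatal", {
  spec <- cohort_spec(n_patients = 1, regimen_mix = c("99999" = 1))
  expect_error(generate_cohort(spec), "99999")
})

test_that("extraction recovers noise-free cohorts exactly", {
  mix <- setNames(c(0.4, 0.3, 0.3),
                  reg[c("FOLFOX", "FULV", "cisplatin+vinorelbine")])
  spec <- cohort_spec(n_patients = 40, regimen_mix = mix,
                      second_line_probability = 0.3,
                      surgery_first_probability = 0.4, seed = 5)
  co <- generate_cohort(spec)
  lib <- builtin_regimen_library()
  res <- extract_episodes(co$bundle, lib)
  got <- res$treatments[order(res$treatments$person_id,
                              res$treatments$start_date), ]
  want <- co$truth$courses[order(co$truth$courses$person_id,
                                 co$truth$courses$start_date), ]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$person_id, want$person_id)
  expect_equal(got$regimen_concept_id, want$regimen_concept_id)
  expect_equal(got$n_cycles, want$n_cycles)
  expect_equal(got$line_number, want$line_number)
  expect_equal(got$start_date, want$start_date)
})

test_that("schedule jitter within the window grace keeps recovery at 100%", {
  mix <- setNames(c(0.5, 0.5), reg[c("FOLFOX", "CapeOx")])
  spec <- cohort_spec(n_patients = 30, regimen_mix = mix,
                      schedule_jitter_days = 7, seed = 13)
  co <- generate_cohort(spec)
  res <- extract_episodes(co$bundle, builtin_regimen_library())
  got <- res$treatments[order(res$treatments$person_id), ]
  want <- co$truth$courses[order(co$truth$courses$person_id), ]
  expect_equal(got$regimen_concept_id, want$regimen_concept_id)
  expect_equal(got$n_cycles, want$n_cycles)
})

test_that("full combination dropout leaves no matchable cycle", {
  spec <- cohort_spec(n_patients = 10,
                      regimen_mix = setNames(1, reg[["FOLFOX"]]),
                      dropout_probability = 1, seed = 3)
  co <- inject_noise(generate_cohort(spec))
  expect_true(all(co$truth$cycles$corrupted))
  cyc <- extract_cycles(co$bundle, builtin_regimen_library())
  expect_equal(nrow(cyc), 0L)
})

test_that("partial dropout removes cycles at roughly the dropout rate", {
  p <- 0.2
  spec <- cohort_spec(n_patients = 60,
                      regimen_mix = setNames(1, reg[["FOLFOX"]]),
                      dropout_probability = p, seed = 29)
  co <- inject_noise(generate_cohort(spec))
  n_true <- nrow(co$truth$cycles)
  cyc <- extract_cycles(co$bundle, builtin_regimen_library())
  frac <- nrow(cyc) / n_true
  tol <- 3 * sqrt(p * (1 - p) / n_true)
  expect_lt(abs(frac - (1 - p)), tol)
  # corrupted cycles are exactly the unmatched ones
  expect_equal(n_true - nrow(cyc), sum(co$truth$cycles$corrupted))
})

test_that("ANC simulation injects detectable nadirs and honest truth", {
  # no dip: no events
  calm <- cohort_spec(n_patients = 5,
                      regimen_mix = setNames(1, reg[["FOLFOX"]]),
                      anc_model = anc_model(nadir_depth_fraction = 1,
                                            nadir_noise_sd = 0),
                      seed = 17)
  expect_equal(nrow(generate_cohort(calm)$truth$events), 0L)

  # deep deterministic dip: every cycle gets a grade-4 nadir
  deep <- cohort_spec(n_patients = 5,
                      regimen_mix = setNames(1, reg[["FOLFOX"]]),
                      anc_model = anc_model(nadir_depth_fraction = 0.05,
                                            nadir_noise_sd = 0),
                      seed = 17)
  co <- generate_cohort(deep)
  expect_equal(nrow(co$truth$events), nrow(co$truth$cycles))
  expect_true(all(co$truth$events$anc_value < 0.5))
  # injected measurements exist on the event dates, off administration days
  ev <- co$truth$events
  for (i in seq_len(nrow(ev))) {
    m <- co$bundle$measurement
    hit <- m$person_id == ev$person_id[i] &
      m$measurement_date == ev$event_date[i] & m$value < 0.5
    expect_true(any(hit))
    sp <- co$bundle$drug_exposure
    sp <- sp[sp$person_id == ev$person_id[i], ]
    expect_false(any(ev$event_date[i] >= sp$start_date &
                       ev$event_date[i] <= sp$end_date))
  }
})

test_that("written cohorts read back into an equivalent bundle", {
  spec <- cohort_spec(n_patients = 6,
                      regimen_mix = setNames(1, reg[["FEC"]]),
                      surgery_first_probability = 0.5,
                      anc_model = anc_model(), seed = 23)
  co <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  bundle <- read_cdm_tables(dir)
  expect_equal(bundle$drug_exposure, co$bundle$drug_exposure)
  expect_equal(bundle$measurement$value, co$bundle$measurement$value)
  expect_equal(bundle$procedure$category, co$bundle$procedure$category)
  truth_back <- readr::read_csv(file.path(dir, "truth_courses.csv"),
                                show_col_types = FALSE)
  expect_equal(nrow(truth_back), nrow(co$truth$courses))
})
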