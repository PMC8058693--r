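reg <- chemo_regimens()
cfg <- cdm_config()

mk_treatments <- function(person, regimen, start_day, n_cycles = 4L,
                          line = 1L, label = NULL) {
  tibble::tibble(
    person_id = as.integer(person),
    regimen_concept_id = as.integer(regimen),
    episode_source_value = if (is.null(label)) as.character(regimen)
      else label,
    start_date = day(start_day),
    end_date = day(start_day + 60L),
    n_cycles = as.integer(n_cycles),
    line_number = as.integer(line))
}

test_that("yearly regimen shares are normalized counts", {
  tr <- dplyr::bind_rows(
    mk_treatments(1:3, reg[["FOLFOX"]], 0L),
    mk_treatments(4L, reg[["FULV"]], 10L))
  out <- regimen_share_by_year(tr)
  expect_equal(out$proportion[out$regimen_concept_id == reg[["FOLFOX"]]],
               0.75)
  expect_equal(out$proportion[out$regimen_concept_id == reg[["FULV"]]],
               0.25)
  expect_equal(sum(out$n), 4L)

  # proportions sum to 1 within every populated year
  set.seed(1)
  tr2 <- mk_treatments(1:50, sample(reg[1:5], 50, replace = TRUE),
                       sample(0:2000, 50))
  sums <- regimen_share_by_year(tr2) |>
    dplyr::group_by(year) |>
    dplyr::summarise(s = sum(proportion))
  expect_true(all(abs(sums$s - 1) < 1e-12))

  expect_equal(nrow(regimen_share_by_year(tr[0, ])), 0L)
})

test_that("cycle-iteration cells below the threshold are suppressed", {
  tr <- dplyr::bind_rows(
    mk_treatments(1:12, reg[["FULV"]], 0L, n_cycles = 6L),
    mk_treatments(13:21, reg[["FOLFOX"]], 0L, n_cycles = 12L))  # 9 < 10
  out <- cycle_iteration_matrix(tr, min_cell = 10L)
  fulv <- out[out$regimen_concept_id == reg[["FULV"]], ]
  expect_equal(fulv$n_patients, 12L)
  expect_false(fulv$suppressed)
  folfox <- out[out$regimen_concept_id == reg[["FOLFOX"]], ]
  expect_true(folfox$suppressed)
  expect_true(is.na(folfox$n_patients))
  # no emitted count below the threshold
  expect_true(all(out$n_patients[!out$suppressed] >= 10L))

  expect_equal(nrow(cycle_iteration_matrix(tr[0, ])), 0L)
})

test_that("trajectories merge, truncate and suppress as specified", {
  # 20 patients: surgery -> FOLFOX -> FOLFIRI (plus a 4th element that
  # must be truncated at depth 3)
  tr <- dplyr::bind_rows(
    mk_treatments(1:20, reg[["FOLFOX"]], 30L, label = "FOLFOX"),
    mk_treatments(1:20, reg[["FOLFIRI"]], 200L, line = 2L,
                  label = "FOLFIRI"),
    mk_treatments(1:20, reg[["FULV"]], 400L, line = 3L, label = "FULV"))
  pr <- tibble::tibble(person_id = 1:20,
                       procedure_concept_id = cfg$surgery_concepts[1],
                       procedure_date = day(0L), category = "SURGERY")
  tj <- build_trajectories(tr, pr, max_depth = 3L, min_node_count = 10L)
  expect_equal(nrow(tj$nodes), 3L)
  expect_equal(tj$nodes$n_patients, rep(20L, 3))
  expect_equal(tj$nodes$percent_of_depth, rep(100, 3))
  expect_equal(tj$nodes$label[order(tj$nodes$depth)],
               c("SURGERY", "FOLFOX", "FOLFIRI"))
  expect_false("FULV" %in% tj$nodes$label)  # 4th element truncated
  expect_equal(nrow(tj$edges), 2L)
  expect_equal(tj$edges$n_patients, rep(20L, 2))

  # consecutive identical labels merge into one element
  dup <- dplyr::bind_rows(
    mk_treatments(1:20, reg[["FOLFOX"]], 30L, label = "FOLFOX"),
    mk_treatments(1:20, reg[["FOLFOX"]], 200L, line = 1L,
                  label = "FOLFOX"))
  tj_dup <- build_trajectories(dup, max_depth = 3L, min_node_count = 10L)
  expect_equal(nrow(tj_dup$nodes), 1L)

  # a 9-patient branch disappears under min_node_count = 10
  branch <- dplyr::bind_rows(
    mk_treatments(1:20, reg[["FOLFOX"]], 0L, label = "FOLFOX"),
    mk_treatments(1:9, reg[["FOLFIRI"]], 200L, line = 2L,
                  label = "FOLFIRI"))
  tj_b <- build_trajectories(branch, max_depth = 3L,
                             min_node_count = 10L)
  expect_false("FOLFIRI" %in% tj_b$nodes$label)
  expect_equal(nrow(tj_b$edges), 0L)
  expect_true(all(tj_b$nodes$n_patients >= 10L))
})

test_that("neutropenia detection applies thresholds and the admin-day rule", {
  meas <- tibble::tibble(
    person_id = c(1L, 1L, 2L, 3L),
    measurement_concept_id = cfg$anc_concepts[1],
    measurement_date = day(c(12L, 19L, 12L, 0L)),
    value = c(0.4, 3.0, 0.8, 0.4),
    unit = "10^9/L")
  cond <- tibble::tibble(person_id = 2L,
                         condition_concept_id =
                           cfg$fever_infection_concepts[1],
                         condition_date = day(12L))
  chemo <- folfox_person(3L, n_cycles = 1L)  # person 3 dosed on day 0
  ev <- detect_cin_fn_events(meas, cond, chemo, cfg)
  expect_equal(ev$event_type[ev$person_id == 1L], "CIN_G4")
  expect_equal(ev$event_type[ev$person_id == 2L], "FN")
  expect_false(3L %in% ev$person_id)  # administration-day exclusion

  # grade-4 value with fever yields both event types for the same day
  both <- detect_cin_fn_events(
    dplyr::mutate(meas[3, ], value = 0.3), cond,
    chemo[0, ], cfg)
  expect_setequal(both$event_type, c("CIN_G4", "FN"))

  # monotone in the threshold: tightening CIN never adds events
  ev_tight <- detect_cin_fn_events(meas, cond, chemo, cfg,
                                   cin_threshold = 0.3)
  cin_loose <- ev[ev$event_type == "CIN_G4", ]
  cin_tight <- ev_tight[ev_tight$event_type == "CIN_G4", ]
  expect_true(nrow(cin_tight) <= nrow(cin_loose))
  expect_true(all(paste(cin_tight$person_id, cin_tight$event_date) %in%
                    paste(cin_loose$person_id, cin_loose$event_date)))
})

test_that("a G-CSF exposure shortly after a low ANC qualifies FN", {
  meas <- tibble::tibble(person_id = 1L,
                         measurement_concept_id = cfg$anc_concepts[1],
                         measurement_date = day(10L), value = 0.8,
                         unit = "10^9/L")
  gcsf <- make_exposures(exposure_rows(1L, cfg$gcsf_concepts[1], 12L))
  no_cond <- tibble::tibble(person_id = integer(),
                            condition_concept_id = integer(),
                            condition_date = as.Date(character()))
  ev <- detect_cin_fn_events(meas, no_cond, gcsf, cfg)
  expect_equal(ev$event_type, "FN")
})

test_that("onset timing bins the first qualifying event per patient", {
  fl <- mk_treatments(1:4, reg[["FOLFOX"]], 0L)
  ev <- tibble::tibble(
    person_id = c(1L, 1L, 2L, 3L, 4L),
    event_date = day(c(10L, 24L, 45L, 1L, 8L)),
    event_type = "CIN_G4",
    anc_value = 0.4)
  out <- onset_timing(ev, fl)
  expect_equal(out$person_id, c(1L, 4L))
  expect_equal(out$gap_days, c(10L, 8L))
  expect_equal(out$bin_label, c("9-15", "2-8"))
  # person 2 beyond the 30-day horizon, person 3 administration-proximal
  expect_false(any(c(2L, 3L) %in% out$person_id))
  # persons with no events are absent
  expect_false(5L %in% out$person_id)
  expect_equal(nrow(onset_timing(ev[0, ], fl)), 0L)
})

test_that("per-cycle incidence uses patients reaching the cycle", {
  lib <- builtin_regimen_library()
  cyc <- dplyr::bind_rows(lapply(1:10, function(p) tibble::tibble(
    person_id = p, regimen_concept_id = unname(reg[["FOLFOX"]]),
    cycle_number = 1:2, start_date = day(c(0L, 14L)))))
  ev <- tibble::tibble(person_id = 1:3, event_date = day(10L),
                       event_type = "CIN_G4", anc_value = 0.4)
  out <- incidence_per_cycle(ev, cyc, lib)
  c1 <- out[out$cycle_number == 1L, ]
  expect_equal(c1$n_at_risk, 10L)
  expect_equal(c1$n_events, 3L)
  expect_equal(c1$incidence, 0.3)
  expect_equal(out$incidence[out$cycle_number == 2L], 0)

  # top-k ranking drops the lowest-frequency regimen
  cyc5 <- dplyr::bind_rows(lapply(1:5, function(r) tibble::tibble(
    person_id = 100L + r, regimen_concept_id = unname(reg[[r]]),
    cycle_number = 1L, start_date = day(0L))))
  ev5 <- tibble::tibble(person_id = 101:104, event_date = day(5L),
                        event_type = "CIN_G4", anc_value = 0.4)
  out5 <- incidence_per_cycle(ev5, cyc5, lib, top_k_regimens = 4L)
  expect_equal(length(unique(out5$regimen_concept_id)), 4L)
  expect_false(unname(reg[[5]]) %in% out5$regimen_concept_id)

  none <- incidence_per_cycle(ev[0, ], cyc, lib)
  expect_true(all(none$incidence == 0))
})

test_that("validation metrics reproduce hand-computed agreement", {
  # 70 evaluable FULV cases, 67 with matching regimen; 30 without
  # information in the gold source
  n <- 100L
  predicted <- tibble::tibble(person_id = 1:n,
                              regimen_concept_id = unname(reg[["FULV"]]),
                              n_cycles = 6L)
  gold <- tibble::tibble(
    person_id = 1:n,
    regimen_concept_id = c(rep(unname(reg[["FULV"]]), 67),
                           rep(unname(reg[["FOLFOX"]]), 3),
                           rep(NA_integer_, 30)),
    n_cycles = 6L)
  m <- validation_metrics(predicted, gold, by_regimen = FALSE)
  expect_equal(m$n_without_information, 30L)
  expect_equal(m$n_evaluable, 70L)
  expect_equal(m$n_regimen_matched, 67L)
  expect_equal(m$ppv, 100 * 67 / 70, tolerance = 1e-12)

  # perfect agreement
  perfect <- validation_metrics(predicted,
                                dplyr::mutate(predicted, n_cycles = 6L),
                                by_regimen = FALSE)
  expect_equal(perfect$ppv, 100)
  expect_equal(perfect$cycle_accuracy, 100)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)

  # cycle differences {0, 1, 2} -> MAE 1, RMSE sqrt(5/3)
  pred3 <- tibble::tibble(person_id = 1:3,
                          regimen_concept_id = unname(reg[["FOLFOX"]]),
                          n_cycles = c(6L, 7L, 8L))
  gold3 <- tibble::tibble(person_id = 1:3,
                          regimen_concept_id = unname(reg[["FOLFOX"]]),
                          n_cycles = 6L)
  m3 <- validation_metrics(pred3, gold3, by_regimen = FALSE)
  expect_equal(m3$mae, 1)
  expect_equal(m3$rmse, sqrt(5 / 3))
  expect_equal(m3$cycle_accuracy, 100 / 3, tolerance = 1e-12)

  expect_warning(validation_metrics(predicted[0, ], gold[0, ]),
                 "no persons")
})

test_that("RMSE never falls below MAE on random agreement tables", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    pred <- tibble::tibble(person_id = 1:n,
                           regimen_concept_id = unname(reg[["FOLFOX"]]),
                           n_cycles = sample(1:12, n, replace = TRUE))
    gold <- tibble::tibble(person_id = 1:n,
                           regimen_concept_id = unname(reg[["FOLFOX"]]),
                           n_cycles = sample(1:12, n, replace = TRUE))
    m <- validation_metrics(pred, gold, by_regimen = FALSE)
    expect_gte(m$rmse, m$mae)
  }
})
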