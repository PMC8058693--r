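ing <- chemo_ingredients()
reg <- chemo_regimens()

test_that("index dates merge multi-day dispenses and stay sorted", {
  lib <- builtin_regimen_library()
  folfox <- lib$definitions[[as.character(reg[["FOLFOX"]])]]
  ex <- make_exposures(exposure_rows(1L, ing[["oxaliplatin"]],
                                     c(0L, 14L, 28L)))
  expect_equal(find_index_dates(ex, folfox), day(c(0L, 14L, 28L)))

  # a day-1 duplicate within min_cycle_gap (5) merges into day 0
  ex2 <- make_exposures(exposure_rows(1L, ing[["oxaliplatin"]],
                                      c(0L, 1L, 14L)))
  expect_equal(find_index_dates(ex2, folfox), day(c(0L, 14L)))

  none <- make_exposures(exposure_rows(1L, ing[["fluorouracil"]], 0L))
  expect_length(find_index_dates(none, folfox), 0L)
})

test_that("cycle matching requires all combination drugs and no exclusions", {
  lib <- builtin_regimen_library()
  folfox <- lib$definitions[[as.character(reg[["FOLFOX"]])]]
  base <- list(
    exposure_rows(1L, ing[["oxaliplatin"]], 0L),
    exposure_rows(1L, ing[["leucovorin"]], 0L),
    exposure_rows(1L, ing[["fluorouracil"]], 0L, duration_days = 2L))

  cyc <- match_cycle(day(0L), make_exposures(base), folfox)
  expect_false(is.null(cyc))
  expect_equal(cyc$start_date, day(0L))
  expect_equal(cyc$end_date, day(1L))  # fluorouracil runs through day 2
  expect_setequal(cyc$component_record_ids, 1:3)

  with_bev <- make_exposures(c(base, list(
    exposure_rows(1L, ing[["bevacizumab"]], 0L))))
  expect_null(match_cycle(day(0L), with_bev, folfox))

  no_fu <- make_exposures(base[1:2])
  expect_null(match_cycle(day(0L), no_fu, folfox))

  # records claimed elsewhere cannot serve as components
  ex <- make_exposures(base)
  expect_null(match_cycle(day(0L), ex, folfox, claimed = 3L))
})

test_that("greedy sequential extraction gives priority regimens the records", {
  lib <- builtin_regimen_library()
  # bevacizumab given every cycle: everything matches FOLFOX-Bev (which
  # is evaluated first, being more specific), nothing matches FOLFOX
  ex <- make_exposures(course_rows(1L, "FOLFOX-Bev", 0L, 4L))
  cyc <- extract_cycles(ex, lib)
  expect_equal(nrow(cyc), 4L)
  expect_true(all(cyc$regimen_concept_id == reg[["FOLFOX-Bev"]]))

  # plain FULV course matches FULV only
  fulv <- make_exposures(course_rows(2L, "FULV", 0L, 6L))
  cyc2 <- extract_cycles(fulv, lib)
  expect_equal(nrow(cyc2), 6L)
  expect_true(all(cyc2$regimen_concept_id == reg[["FULV"]]))

  expect_equal(nrow(extract_cycles(folfox_person()[0, ], lib)), 0L)
})

test_that("no record is claimed by two cycles", {
  lib <- builtin_regimen_library()
  ex <- make_exposures(course_rows(1L, "FOLFOX", 0L, 12L),
                       course_rows(1L, "FOLFIRI", 200L, 6L),
                       course_rows(2L, "CapeOx", 10L, 8L))
  cyc <- extract_cycles(ex, lib)
  all_ids <- unlist(cyc$component_record_ids)
  expect_equal(anyDuplicated(all_ids), 0L)
})

test_that("adding an exclusion exposure never increases matches", {
  lib <- builtin_regimen_library()
  ex <- make_exposures(course_rows(1L, "FOLFOX", 0L, 6L))
  n_before <- sum(extract_cycles(ex, lib)$regimen_concept_id ==
                    reg[["FOLFOX"]])
  with_bev <- make_exposures(
    course_rows(1L, "FOLFOX", 0L, 6L),
    exposure_rows(1L, ing[["bevacizumab"]], 28L))
  n_after <- sum(extract_cycles(with_bev, lib)$regimen_concept_id ==
                   reg[["FOLFOX"]])
  expect_lt(n_after, n_before)
})

test_that("cycles collapse by the gap rule and renumber from 1", {
  lib <- builtin_regimen_library()
  # 12 cycles q14d, window 21 -> one treatment episode of 12
  cyc <- extract_cycles(folfox_person(n_cycles = 12L), lib)
  col <- collapse_to_treatment_episodes(cyc, lib)
  expect_equal(nrow(col$treatments), 1L)
  expect_equal(col$treatments$n_cycles, 12L)
  expect_equal(sort(col$cycles$cycle_number), 1:12)

  # starts at day 0, 14, 120: the 106-day gap splits the course
  ex <- make_exposures(course_rows(1L, "FOLFOX", 0L, 2L),
                       course_rows(1L, "FOLFOX", 120L, 1L))
  col2 <- collapse_to_treatment_episodes(extract_cycles(ex, lib), lib)
  expect_equal(sort(col2$treatments$n_cycles), c(1L, 2L))
  expect_equal(
    col2$cycles$cycle_number[order(col2$cycles$start_date)],
    c(1L, 2L, 1L))

  single <- collapse_to_treatment_episodes(
    extract_cycles(folfox_person(n_cycles = 1L), lib), lib)
  expect_equal(single$treatments$n_cycles, 1L)
  expect_equal(single$cycles$cycle_number, 1L)
})

test_that("treatment lines advance on regimen change or long gaps", {
  lib <- builtin_regimen_library()
  # FOLFOX then FOLFIRI -> lines 1, 2
  ex <- make_exposures(course_rows(1L, "FOLFOX", 0L, 4L),
                       course_rows(1L, "FOLFIRI", 100L, 4L))
  tr <- assign_treatment_lines(
    collapse_to_treatment_episodes(extract_cycles(ex, lib),
                                   lib)$treatments, lib)
  tr <- tr[order(tr$start_date), ]
  expect_equal(tr$regimen_concept_id,
               unname(reg[c("FOLFOX", "FOLFIRI")]))
  expect_equal(tr$line_number, c(1L, 2L))

  # same regimen restarted 300 days later (line window 120) -> lines 1, 2
  ex2 <- make_exposures(course_rows(2L, "FOLFOX", 0L, 2L),
                        course_rows(2L, "FOLFOX", 300L, 2L))
  tr2 <- assign_treatment_lines(
    collapse_to_treatment_episodes(extract_cycles(ex2, lib),
                                   lib)$treatments, lib)
  expect_equal(sort(tr2$line_number), c(1L, 2L))

  tr3 <- assign_treatment_lines(
    collapse_to_treatment_episodes(
      extract_cycles(folfox_person(3L, n_cycles = 2L), lib),
      lib)$treatments, lib)
  expect_equal(tr3$line_number, 1L)
})

test_that("end-to-end extraction emits a consistent episode table", {
  lib <- builtin_regimen_library()
  res <- extract_episodes(cdm_bundle(folfox_person(n_cycles = 5L)), lib)
  cfg <- cdm_config()
  tr_rows <- res$episodes[res$episodes$episode_concept_id ==
                            cfg$treatment_episode_concept_id, ]
  cy_rows <- res$episodes[res$episodes$episode_concept_id ==
                            cfg$cycle_episode_concept_id, ]
  expect_equal(nrow(tr_rows), 1L)
  expect_equal(nrow(cy_rows), 5L)
  expect_true(all(cy_rows$episode_parent_id == tr_rows$episode_id))
  expect_true(all(tr_rows$episode_start_date <= cy_rows$episode_start_date))
  expect_true(all(tr_rows$episode_end_date >= cy_rows$episode_end_date))
  expect_equal(cy_rows$episode_number[order(cy_rows$episode_start_date)],
               1:5)
  # every component drug record appears exactly once in EPISODE_EVENT
  expect_equal(sort(res$events$event_id),
               sort(unlist(res$cycles$component_record_ids)))
})

test_that("extraction is invariant to input row order and persons are independent", {
  lib <- builtin_regimen_library()
  ex <- make_exposures(course_rows(1L, "FOLFOX", 0L, 3L),
                       course_rows(2L, "FULV", 5L, 4L))
  res <- extract_episodes(cdm_bundle(ex), lib)
  set.seed(99)
  shuffled <- ex[sample(nrow(ex)), ]
  res_shuffled <- extract_episodes(cdm_bundle(shuffled), lib)
  expect_equal(res_shuffled$episodes, res$episodes)
  expect_equal(res_shuffled$events, res$events)

  # union of per-person runs equals the joint run
  r1 <- extract_episodes(cdm_bundle(ex), lib, persons = 1L)
  r2 <- extract_episodes(cdm_bundle(ex), lib, persons = 2L)
  joint <- dplyr::bind_rows(
    r1$episodes[, c("person_id", "episode_concept_id",
                    "episode_start_date", "episode_end_date",
                    "episode_number", "episode_object_concept_id")],
    r2$episodes[, c("person_id", "episode_concept_id",
                    "episode_start_date", "episode_end_date",
                    "episode_number", "episode_object_concept_id")])
  both <- res$episodes[, names(joint)]
  expect_equal(dplyr::arrange(joint, person_id, episode_start_date,
                              episode_concept_id),
               dplyr::arrange(both, person_id, episode_start_date,
                              episode_concept_id))
})

test_that("re-running extraction writes byte-identical episode files", {
  lib <- builtin_regimen_library()
  ex <- make_exposures(course_rows(1L, "FOLFOX", 0L, 4L),
                       course_rows(2L, "AC", 30L, 4L))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res1 <- extract_episodes(cdm_bundle(ex), lib)
  write_episode_tables(res1$episodes, res1$events, d1)
  res2 <- extract_episodes(cdm_bundle(ex), lib)
  write_episode_tables(res2$episodes, res2$events, d2)
  for (f in c("EPISODE.csv", "EPISODE_EVENT.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("the engine matches the brute-force reference on random instances", {
  set.seed(2024)
  for (case_i in 1:40) {
    case <- random_case()
    got <- cycles_to_comparable(extract_cycles(case$exposures,
                                               case$library))
    want <- oracle_extract_cycles(case$exposures, case$library)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want,
                     info = sprintf("random case %d", case_i))
  }
})
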