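# Synthetic OMOP-shaped cohort generator with ground truth.
#
# The generator emulates the structure of hospital EHR chemotherapy
# data: per-patient ingredient-level drug exposures laid out along the
# knowledge base's per-cycle schedule templates (the same templates the
# matcher documentation describes, so generator and matcher share one
# source of truth), optional surgery before chemotherapy, an optional
# second-line course, weekly ANC measurement series with post-cycle
# nadir dips, fever diagnoses and G-CSF exposures accompanying severe
# neutropenia. Everything the generator injects is recorded in a
# ground-truth object so that extraction and analytics can be validated
# against known answers.
#
# Randomness: one root seed; each patient uses an independent substream
# seeded from (root seed, patient index), so increasing n_patients
# appends patients without reshuffling earlier ones.

#' ANC simulation model parameters
#'
#' Baseline parameters are in cells per microlitre, matching how EHR
#' laboratories report them (e.g. a colorectal-cancer population mean
#' near 5582 cells/uL); emitted measurements are normalized to
#' `10^9` cells/L. The post-cycle dip is parameterized by the nadir day
#' (days after cycle start) and the fraction of baseline remaining at
#' nadir: a `nadir_depth_fraction` near 1 means no dip, a small
#' fraction drives the nadir below the grade-4 threshold of
#' `0.5 x 10^9`/L for most baselines.
#'
#' @param baseline_mean,baseline_sd Baseline ANC (cells/uL); draws are
#'   truncated below at 1500 cells/uL so that background measurements
#'   never cross event thresholds by themselves.
#' @param nadir_day_mean,nadir_day_sd Nadir day offset after cycle
#'   start (days).
#' @param nadir_depth_fraction Fraction of baseline remaining at nadir,
#'   in (0, 1].
#' @param nadir_noise_sd Multiplicative log-normal noise on the nadir
#'   value (sd on the log scale; 0 for a deterministic depth).
#' @param measurement_cadence_days Background measurement cadence
#'   (default weekly).
#' @param fn_fever_probability_given_grade4 Probability that a grade-4
#'   nadir is accompanied by a fever/infection diagnosis on the nadir
#'   day.
#' @param gcsf_probability_given_grade4 Probability that a grade-4
#'   nadir is followed by a G-CSF exposure the next day.
#' @return A list of class `anc_model`.
#' @export
anc_model <- function(baseline_mean = 5582, baseline_sd = 4403,
                      nadir_day_mean = 10, nadir_day_sd = 2,
                      nadir_depth_fraction = 0.2,
                      nadir_noise_sd = 0.3,
                      measurement_cadence_days = 7L,
                      fn_fever_probability_given_grade4 = 0.3,
                      gcsf_probability_given_grade4 = 0.2) {
  stopifnot(nadir_depth_fraction > 0, nadir_depth_fraction <= 1,
            nadir_day_mean >= 1, nadir_day_mean <= 30)
  structure(list(
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    nadir_day_mean = nadir_day_mean, nadir_day_sd = nadir_day_sd,
    nadir_depth_fraction = nadir_depth_fraction,
    nadir_noise_sd = nadir_noise_sd,
    measurement_cadence_days = as.integer(measurement_cadence_days),
    fn_fever_probability_given_grade4 = fn_fever_probability_given_grade4,
    gcsf_probability_given_grade4 = gcsf_probability_given_grade4
  ), class = "anc_model")
}

#' Cohort simulation specification
#'
#' @param n_patients Number of patients.
#' @param regimen_mix Named numeric vector: regimen concept ID (as
#'   name) to sampling probability; must sum to 1.
#' @param cycles_per_course Optional named integer vector overriding
#'   the knowledge base's default cycle count per regimen.
#' @param schedule_jitter_days Non-negative integer: each cycle start
#'   is delayed by a uniform draw in `0..schedule_jitter_days`
#'   (whole-cycle shift; delays within the 7-day grace of the cycle
#'   window keep extraction recovery at 100%).
#' @param dropout_probability Probability, applied per cycle by
#'   [inject_noise()], of removing one combination-drug record of the
#'   cycle (making it unmatchable).
#' @param second_line_probability Probability that a patient proceeds
#'   to a second-line course.
#' @param second_line_map Named integer vector mapping a first-line
#'   regimen concept ID to its successor regimen.
#' @param surgery_first_probability Probability of a surgery procedure
#'   30-90 days before the first chemotherapy.
#' @param anc_model An [anc_model()], or `NULL` to skip ANC simulation.
#' @param year_range Length-2 integer: first treatment dates are drawn
#'   uniformly over this calendar-year range (default 2008-2018, to
#'   exercise the by-year analytics).
#' @param seed Root seed (integer).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        regimen_mix = c("2001" = 1),
                        cycles_per_course = NULL,
                        schedule_jitter_days = 0L,
                        dropout_probability = 0,
                        second_line_probability = 0,
                        second_line_map = default_second_line_map(),
                        surgery_first_probability = 0,
                        anc_model = NULL,
                        year_range = c(2008L, 2018L),
                        seed = 1L) {
  stopifnot(n_patients >= 0, !is.null(names(regimen_mix)),
            all(regimen_mix >= 0), abs(sum(regimen_mix) - 1) < 1e-8,
            schedule_jitter_days >= 0,
            dropout_probability >= 0, dropout_probability <= 1,
            second_line_probability >= 0, second_line_probability <= 1,
            surgery_first_probability >= 0, surgery_first_probability <= 1,
            length(year_range) == 2L)
  structure(list(
    n_patients = as.integer(n_patients),
    regimen_mix = regimen_mix,
    cycles_per_course = cycles_per_course,
    schedule_jitter_days = as.integer(schedule_jitter_days),
    dropout_probability = dropout_probability,
    second_line_probability = second_line_probability,
    second_line_map = second_line_map,
    surgery_first_probability = surgery_first_probability,
    anc_model = anc_model,
    year_range = as.integer(year_range),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default successor-regimen map for second-line courses
#' @return Named integer vector (first-line regimen concept ID to
#'   second-line regimen concept ID), over the built-in library.
#' @export
default_second_line_map <- function() {
  reg <- chemo_regimens()
  c(setNames(reg[["FOLFIRI"]], reg[["FOLFOX"]]),
    setNames(reg[["FULV"]], reg[["CapeOx"]]),
    setNames(reg[["paclitaxel mono"]], reg[["AC"]]),
    setNames(reg[["docetaxel mono"]], reg[["FEC"]]),
    setNames(reg[["docetaxel mono"]], reg[["FAC"]]),
    setNames(reg[["gefitinib mono"]], reg[["cisplatin+vinorelbine"]]),
    setNames(reg[["gefitinib mono"]], reg[["cisplatin+pemetrexed"]]),
    setNames(reg[["carboplatin+paclitaxel"]],
             reg[["carboplatin+gemcitabine"]]),
    setNames(reg[["docetaxel mono"]], reg[["carboplatin+paclitaxel"]]))
}

patient_seed <- function(root_seed, i) {
  (abs(root_seed) * 100003L + i * 7919L) %% 2147483629L
}

admin_day_offsets <- function(schedule) {
  unique(unlist(lapply(schedule$components, function(cmp) {
    unlist(lapply(cmp$day_offsets, function(o) o + seq_len(cmp$duration_days) - 1L))
  })))
}

#' Generate a synthetic cohort with ground truth
#'
#' @param spec A [cohort_spec()].
#' @param library A [regimen_library()] whose definitions carry
#'   schedule templates; defaults to [builtin_regimen_library()].
#' @param config A [cdm_config()] supplying the synthetic procedure,
#'   condition and measurement concept IDs.
#' @return A list of class `synthetic_cohort` with elements `bundle`
#'   (a [cdm_bundle()], ingredient-level, ANC already normalized to
#'   `10^9`/L) and `truth` (list of tibbles `patients`, `courses`,
#'   `cycles`, `events`).
#' @export
generate_cohort <- function(spec, library = builtin_regimen_library(),
                            config = cdm_config()) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(library, "regimen_library"))
  mix_ids <- as.integer(names(spec$regimen_mix))
  missing <- setdiff(mix_ids, as.integer(names(library$definitions)))
  if (length(missing) > 0L) {
    stop("regimen_mix references regimen(s) absent from the library: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (id in union(mix_ids, spec$second_line_map)) {
    def <- library$definitions[[as.character(id)]]
    if (!is.null(def) && is.null(def$schedule)) {
      stop("regimen ", id, " has no schedule template", call. = FALSE)
    }
  }

  day0 <- as.Date(sprintf("%d-01-01", spec$year_range[1]))
  day1 <- as.Date(sprintf("%d-12-31", spec$year_range[2]))
  n_days <- as.integer(day1 - day0)

  exposures <- list(); measurements <- list(); conditions <- list()
  procedures <- list()
  t_patients <- list(); t_courses <- list(); t_cycles <- list()
  t_events <- list()

  for (i in seq_len(spec$n_patients)) {
    set.seed(patient_seed(spec$seed, i))
    person <- i
    r1 <- mix_ids[sample.int(length(mix_ids), 1L,
                             prob = spec$regimen_mix)]
    first_date <- day0 + sample.int(n_days + 1L, 1L) - 1L

    course_plan <- list(list(regimen = r1, line = 1L,
                             start = first_date))
    if (spec$second_line_probability > 0 &&
        runif(1) < spec$second_line_probability) {
      r2 <- spec$second_line_map[as.character(r1)]
      if (!is.na(r2)) course_plan[[2]] <- list(regimen = as.integer(r2),
                                               line = 2L, start = NA)
    }

    if (spec$surgery_first_probability > 0 &&
        runif(1) < spec$surgery_first_probability) {
      sdate <- first_date - sample(30:90, 1L)
      procedures[[length(procedures) + 1L]] <- tibble::tibble(
        person_id = person,
        procedure_concept_id = config$surgery_concepts[1],
        procedure_date = sdate, category = "SURGERY")
    }

    pexp <- list(); pcyc <- list()
    course_start <- first_date
    for (ci in seq_along(course_plan)) {
      plan <- course_plan[[ci]]
      def <- library$definitions[[as.character(plan$regimen)]]
      sch <- def$schedule
      k <- spec$cycles_per_course[[as.character(plan$regimen)]] %||%
        sch$n_cycles_default
      jits <- if (spec$schedule_jitter_days > 0) {
        sample(0:spec$schedule_jitter_days, k, replace = TRUE)
      } else rep(0L, k)
      cycle_starts <- course_start +
        (seq_len(k) - 1L) * sch$cycle_length_days + jits
      last_offset <- max(vapply(sch$components, function(cmp)
        max(cmp$day_offsets) + cmp$duration_days - 1L, integer(1)))
      for (cmp in sch$components) {
        n_off <- length(cmp$day_offsets)
        s <- rep(cycle_starts, each = n_off) +
          rep(cmp$day_offsets, times = k)
        pexp[[length(pexp) + 1L]] <- tibble::tibble(
          person_id = person,
          drug_concept_id = cmp$ingredient_concept_id,
          ingredient_concept_id = cmp$ingredient_concept_id,
          start_date = s, end_date = s + cmp$duration_days - 1L)
      }
      cyc_df <- tibble::tibble(
        person_id = person, course_index = ci,
        regimen_concept_id = def$regimen_concept_id,
        cycle_number = seq_len(k), start_date = cycle_starts,
        end_date = cycle_starts + last_offset, corrupted = FALSE)
      pcyc[[length(pcyc) + 1L]] <- cyc_df
      t_courses[[length(t_courses) + 1L]] <- tibble::tibble(
        person_id = person, course_index = ci,
        regimen_concept_id = def$regimen_concept_id,
        line_number = plan$line, n_cycles = k,
        start_date = min(cyc_df$start_date),
        end_date = max(cyc_df$end_date))
      # next course starts 30-60 days after this one ends
      course_start <- max(cyc_df$end_date) + sample(30:60, 1L)
    }
    pcyc_df <- dplyr::bind_rows(pcyc)
    t_cycles[[length(t_cycles) + 1L]] <- pcyc_df
    pexp_df <- dplyr::bind_rows(pexp)
    exposures[[length(exposures) + 1L]] <- pexp_df

    # --- ANC series and injected neutropenia events ---
    if (!is.null(spec$anc_model)) {
      am <- spec$anc_model
      baseline <- max(1500, rnorm(1, am$baseline_mean, am$baseline_sd))
      spans <- pexp_df[, c("start_date", "end_date")]
      on_admin <- function(d) any(d >= spans$start_date &
                                  d <= spans$end_date)
      last_day <- max(pexp_df$end_date) + 30L
      bg_days <- seq(first_date, last_day,
                     by = am$measurement_cadence_days)
      bg_vals <- baseline * runif(length(bg_days), 0.9, 1.1)
      measurements[[length(measurements) + 1L]] <- tibble::tibble(
        person_id = person, measurement_concept_id = config$anc_concepts[1],
        measurement_date = bg_days, value = bg_vals / 1000,
        unit = "10^9/L")
      for (j in seq_len(nrow(pcyc_df))) {
        cstart <- pcyc_df$start_date[j]
        nd <- round(rnorm(1, am$nadir_day_mean, am$nadir_day_sd))
        nd <- min(max(nd, 2L), 29L)
        # draw these before any skip so the stream is fixed per cycle
        noise <- if (am$nadir_noise_sd > 0)
          exp(rnorm(1, 0, am$nadir_noise_sd)) else 1
        u_fever <- runif(1); u_gcsf <- runif(1)
        while (nd <= 29L && on_admin(cstart + nd)) nd <- nd + 1L
        if (nd > 29L) next
        nadir_val <- baseline * am$nadir_depth_fraction * noise
        ndate <- cstart + nd
        measurements[[length(measurements) + 1L]] <- tibble::tibble(
          person_id = person,
          measurement_concept_id = config$anc_concepts[1],
          measurement_date = ndate, value = nadir_val / 1000,
          unit = "10^9/L")
        if (nadir_val < 500) {
          fever <- u_fever < am$fn_fever_probability_given_grade4
          gcsf <- u_gcsf < am$gcsf_probability_given_grade4
          if (fever) {
            conditions[[length(conditions) + 1L]] <- tibble::tibble(
              person_id = person,
              condition_concept_id = config$fever_infection_concepts[1],
              condition_date = ndate)
          }
          if (gcsf) {
            exposures[[length(exposures) + 1L]] <- tibble::tibble(
              person_id = person,
              drug_concept_id = config$gcsf_concepts[1],
              ingredient_concept_id = config$gcsf_concepts[1],
              start_date = ndate + 1L, end_date = ndate + 1L)
          }
          t_events[[length(t_events) + 1L]] <- tibble::tibble(
            person_id = person, event_date = ndate,
            event_type = "CIN_G4",
            anc_value = nadir_val / 1000,
            fever = fever, gcsf = gcsf,
            course_index = pcyc_df$course_index[j],
            cycle_number = pcyc_df$cycle_number[j],
            gap_days = as.integer(ndate - first_date))
        }
      }
    }

    t_patients[[length(t_patients) + 1L]] <- tibble::tibble(
      person_id = person, first_chemo_date = first_date,
      first_regimen_concept_id = r1)
  }

  bind_or <- function(lst, proto) {
    if (length(lst) == 0L) proto else dplyr::bind_rows(lst)
  }
  exp_df <- bind_or(exposures, empty_drug_exposure())
  if (nrow(exp_df) > 0L) {
    exp_df <- exp_df[order(exp_df$person_id, exp_df$start_date,
                           exp_df$ingredient_concept_id,
                           exp_df$end_date), , drop = FALSE]
    exp_df$record_id <- seq_len(nrow(exp_df))
  } else {
    exp_df <- empty_drug_exposure()
  }
  bundle <- cdm_bundle(
    drug_exposure = exp_df,
    measurement = bind_or(measurements, empty_measurement()),
    condition = bind_or(conditions, empty_condition()),
    procedure = bind_or(procedures, empty_procedure()))

  truth <- list(
    patients = bind_or(t_patients, tibble::tibble(
      person_id = integer(), first_chemo_date = as.Date(character()),
      first_regimen_concept_id = integer())),
    courses = bind_or(t_courses, tibble::tibble(
      person_id = integer(), course_index = integer(),
      regimen_concept_id = integer(), line_number = integer(),
      n_cycles = integer(), start_date = as.Date(character()),
      end_date = as.Date(character()))),
    cycles = bind_or(t_cycles, tibble::tibble(
      person_id = integer(), course_index = integer(),
      regimen_concept_id = integer(), cycle_number = integer(),
      start_date = as.Date(character()), end_date = as.Date(character()),
      corrupted = logical())),
    events = bind_or(t_events, tibble::tibble(
      person_id = integer(), event_date = as.Date(character()),
      event_type = character(), anc_value = numeric(),
      fever = logical(), gcsf = logical(), course_index = integer(),
      cycle_number = integer(), gap_days = integer())))

  structure(list(bundle = bundle, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patient(s), %d exposure(s), %d true cycle(s), %d injected event(s)\n",
    nrow(x$truth$patients), nrow(x$bundle$drug_exposure),
    nrow(x$truth$cycles), nrow(x$truth$events)))
  invisible(x)
}

#' Corrupt a cohort with combination-drug dropout
#'
#' For each true cycle of a regimen that has combination drugs,
#' independently with probability `spec$dropout_probability`, one
#' combination-drug record of the cycle is removed from the bundle,
#' which makes that cycle unmatchable by the extraction engine. The
#' returned truth marks the corrupted cycles.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param spec The [cohort_spec()] (for `dropout_probability` and
#'   `seed`); defaults to the cohort's own spec.
#' @param library Library supplying drug roles; default built-in.
#' @return A `synthetic_cohort` with thinned exposures and annotated
#'   truth.
#' @export
inject_noise <- function(cohort, spec = cohort$spec,
                         library = builtin_regimen_library()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  p <- spec$dropout_probability
  if (p == 0 || nrow(cohort$truth$cycles) == 0L) return(cohort)
  set.seed((spec$seed * 131071L + 9973L) %% 2147483629L)
  exp_df <- cohort$bundle$drug_exposure
  cycles <- cohort$truth$cycles
  drop_ids <- integer()
  hit <- runif(nrow(cycles)) < p
  for (j in which(hit)) {
    def <- library$definitions[[as.character(cycles$regimen_concept_id[j])]]
    if (is.null(def) || length(def$combination_drugs) == 0L) next
    in_cycle <- exp_df$person_id == cycles$person_id[j] &
      exp_df$start_date >= cycles$start_date[j] &
      exp_df$start_date <= cycles$end_date[j] &
      exp_df$ingredient_concept_id %in% def$combination_drugs
    ids <- exp_df$record_id[in_cycle]
    if (length(ids) == 0L) next
    drop_ids <- c(drop_ids, ids[1])
    cycles$corrupted[j] <- TRUE
  }
  cohort$bundle$drug_exposure <-
    exp_df[!(exp_df$record_id %in% drop_ids), , drop = FALSE]
  cohort$truth$cycles <- cycles
  cohort
}

#' Write a synthetic cohort to a CDM directory
#'
#' Emits `DRUG_EXPOSURE.csv`, `MEASUREMENT.csv`,
#' `CONDITION_OCCURRENCE.csv` and `PROCEDURE_OCCURRENCE.csv` with OMOP
#' v5.3 column names, plus ground-truth files
#' (`truth_patients.csv`, `truth_courses.csv`, `truth_cycles.csv`,
#' `truth_events.csv`).
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  b <- cohort$bundle
  readr::write_csv(tibble::tibble(
    drug_exposure_id = b$drug_exposure$record_id,
    person_id = b$drug_exposure$person_id,
    drug_concept_id = b$drug_exposure$drug_concept_id,
    drug_exposure_start_date = b$drug_exposure$start_date,
    drug_exposure_end_date = b$drug_exposure$end_date),
    file.path(directory, "DRUG_EXPOSURE.csv"), progress = FALSE)
  readr::write_csv(tibble::tibble(
    person_id = b$measurement$person_id,
    measurement_concept_id = b$measurement$measurement_concept_id,
    measurement_date = b$measurement$measurement_date,
    value_as_number = b$measurement$value,
    unit_source_value = b$measurement$unit),
    file.path(directory, "MEASUREMENT.csv"), progress = FALSE)
  readr::write_csv(tibble::tibble(
    person_id = b$condition$person_id,
    condition_concept_id = b$condition$condition_concept_id,
    condition_start_date = b$condition$condition_date),
    file.path(directory, "CONDITION_OCCURRENCE.csv"), progress = FALSE)
  readr::write_csv(tibble::tibble(
    person_id = b$procedure$person_id,
    procedure_concept_id = b$procedure$procedure_concept_id,
    procedure_date = b$procedure$procedure_date),
    file.path(directory, "PROCEDURE_OCCURRENCE.csv"), progress = FALSE)
  for (nm in names(cohort$truth)) {
    readr::write_csv(cohort$truth[[nm]],
                     file.path(directory, paste0("truth_", nm, ".csv")),
                     progress = FALSE)
  }
  invisible(directory)
}
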