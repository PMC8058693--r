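# Temporal matching engine: converts ingredient-level drug exposure
# records into regimen-level cycle episodes, treatment episodes, and
# treatment lines.
#
# The algorithm, per regimen and person:
#   1. index dates  - every dispense date of an index drug opens a
#      candidate cycle (near-duplicate dates merged, see
#      min_cycle_gap_days);
#   2. cycle match  - a candidate matches when every combination drug is
#      dispensed and no exclusion drug is dispensed inside the cycle
#      window;
#   3. episode dates - cycle start = index-drug start, end = last
#      component end;
#   4. collapse/lines - chronological cycles with start gaps within the
#      cycle window collapse into one treatment episode (cycle numbers
#      1..k); treatment lines advance on regimen change or a start gap
#      beyond the line window.
#
# Regimens are evaluated sequentially in the library's evaluation
# order; records claimed as components by an earlier regimen cannot
# serve as index or combination components for a later one (greedy
# consumption; prevents one administration counting toward two
# regimens). Exclusion drugs are tested against ALL exposures in the
# window, claimed or not: exclusion expresses "this drug was
# co-administered", regardless of claiming.
#
# Window convention: day-inclusive interval
# [index_date, index_date + cycle_window_days - 1], evaluated on
# exposure START dates, truncated at the next index date of the same
# regimen so that the grace window of one cycle cannot swallow the
# components of the next.
#
# The engine contains no randomness and fixed sort keys everywhere:
# identical inputs (in any row order) give identical outputs.

days_between <- function(later, earlier) {
  as.integer(later) - as.integer(earlier)
}

#' Identify candidate cycle index dates for one person and regimen
#'
#' Scans the person's exposures for starts of the regimen's index
#' drug(s) and returns the distinct dates in ascending order, merging
#' any date closer than `min_cycle_gap_days` to the previously retained
#' date into that date (multi-day dispensing of one administration must
#' not open two cycles; the earlier date wins).
#'
#' @param exposures One person's drug-exposure tibble (ingredient-rolled;
#'   exclude already-claimed records before calling if claiming
#'   semantics apply).
#' @param regimen A [regimen_definition()].
#' @return `Date` vector of retained index dates (possibly empty).
#' @export
find_index_dates <- function(exposures, regimen) {
  starts <- exposures$start_date[
    exposures$ingredient_concept_id %in% regimen$index_drugs]
  if (length(starts) == 0L) return(as.Date(character()))
  starts <- sort(unique(starts))
  keep <- starts[1]
  for (d in starts[-1]) {
    if (days_between(d, keep[length(keep)]) >= regimen$min_cycle_gap_days) {
      keep <- c(keep, d)
    }
  }
  as.Date(keep, origin = "1970-01-01")
}

#' Attempt to match one treatment cycle at an index date
#'
#' The cycle window is `[index_date, window_end]` with `window_end`
#' defaulting to `index_date + cycle_window_days - 1` (callers iterate
#' over index dates and truncate at the next index date). The match
#' succeeds iff, among exposures *starting* in the window:
#' unclaimed exposures cover at least one index drug and every
#' combination drug, and no exposure of an exclusion drug (claimed or
#' not) is present. On success the unclaimed index and combination
#' exposures in the window are the cycle's components.
#'
#' @param index_date Candidate day 1 (from [find_index_dates()]).
#' @param exposures One person's drug-exposure tibble.
#' @param regimen A [regimen_definition()].
#' @param claimed Integer vector of record IDs already claimed by
#'   previously matched cycles.
#' @param window_end Optional last day of the window (Date).
#' @return A list describing the cycle (fields `person_id`,
#'   `regimen_concept_id`, `index_date`, `start_date`, `end_date`,
#'   `component_record_ids`) or `NULL` when the cycle does not match.
#' @export
match_cycle <- function(index_date, exposures, regimen,
                        claimed = integer(), window_end = NULL) {
  if (is.null(window_end)) {
    window_end <- index_date + regimen$cycle_window_days - 1L
  }
  in_window <- exposures$start_date >= index_date &
    exposures$start_date <= window_end
  if (any(in_window &
          exposures$ingredient_concept_id %in% regimen$exclusion_drugs)) {
    return(NULL)
  }
  candidate <- in_window &
    !(exposures$record_id %in% claimed) &
    exposures$ingredient_concept_id %in% component_drugs(regimen)
  cand <- exposures[candidate, , drop = FALSE]
  idx_rows <- cand$ingredient_concept_id %in% regimen$index_drugs
  if (!any(idx_rows)) return(NULL)
  if (!all(regimen$combination_drugs %in% cand$ingredient_concept_id)) {
    return(NULL)
  }
  list(
    person_id = cand$person_id[1],
    regimen_concept_id = regimen$regimen_concept_id,
    index_date = index_date,
    start_date = min(cand$start_date[idx_rows]),
    end_date = max(cand$end_date),
    component_record_ids = sort(cand$record_id)
  )
}

#' Extract all matched cycles for a cohort
#'
#' Runs the sequential greedy extraction: for each person, regimens are
#' evaluated in the library's evaluation order; for each regimen, index
#' dates are identified among still-unclaimed exposures and matched one
#' by one (windows truncated at the next index date); components of a
#' matched cycle are claimed and unavailable to later regimens.
#'
#' @param x A [cdm_bundle()] or a drug-exposure tibble.
#' @param library A [regimen_library()].
#' @param persons Optional integer vector restricting extraction to
#'   these person IDs.
#' @return Tibble of matched cycles, sorted by (person, start date):
#'   columns `person_id`, `regimen_concept_id`, `index_date`,
#'   `start_date`, `end_date` and list-column `component_record_ids`.
#'   Attribute `unmatched_index_dates` is a tibble of index dates whose
#'   cycle did not match (combination drug missing or exclusion drug
#'   present), for log summaries.
#' @export
extract_cycles <- function(x, library, persons = NULL) {
  stopifnot(inherits(library, "regimen_library"))
  exposures <- if (inherits(x, "cdm_bundle")) x$drug_exposure else
    tibble::as_tibble(x)
  if (!is.null(persons)) {
    exposures <- exposures[exposures$person_id %in% persons, , drop = FALSE]
  }
  exposures <- exposures[order(exposures$person_id, exposures$start_date,
                               exposures$record_id), , drop = FALSE]
  out <- list()
  unmatched <- list()
  for (pex in split(exposures, exposures$person_id)) {
    claimed <- integer()
    for (rid in library$evaluation_order) {
      def <- library$definitions[[as.character(rid)]]
      unclaimed <- pex[!(pex$record_id %in% claimed), , drop = FALSE]
      idx <- find_index_dates(unclaimed, def)
      if (length(idx) == 0L) next
      for (i in seq_along(idx)) {
        wend <- idx[i] + def$cycle_window_days - 1L
        if (i < length(idx)) wend <- min(wend, idx[i + 1L] - 1L)
        cyc <- match_cycle(idx[i], pex, def, claimed, window_end = wend)
        if (is.null(cyc)) {
          unmatched[[length(unmatched) + 1L]] <- tibble::tibble(
            person_id = pex$person_id[1], regimen_concept_id = rid,
            index_date = idx[i])
        } else {
          claimed <- c(claimed, cyc$component_record_ids)
          out[[length(out) + 1L]] <- cyc
        }
      }
    }
  }
  cycles <- if (length(out) == 0L) empty_cycles() else tibble::tibble(
    person_id = vapply(out, `[[`, integer(1), "person_id"),
    regimen_concept_id = vapply(out, `[[`, integer(1),
                                "regimen_concept_id"),
    index_date = as.Date(vapply(out, function(c) as.integer(c$index_date),
                                integer(1)), origin = "1970-01-01"),
    start_date = as.Date(vapply(out, function(c) as.integer(c$start_date),
                                integer(1)), origin = "1970-01-01"),
    end_date = as.Date(vapply(out, function(c) as.integer(c$end_date),
                              integer(1)), origin = "1970-01-01"),
    component_record_ids = lapply(out, `[[`, "component_record_ids")
  )
  cycles <- cycles[order(cycles$person_id, cycles$start_date,
                         cycles$regimen_concept_id), , drop = FALSE]
  attr(cycles, "unmatched_index_dates") <- if (length(unmatched) == 0L) {
    tibble::tibble(person_id = integer(), regimen_concept_id = integer(),
                   index_date = as.Date(character()))
  } else dplyr::bind_rows(unmatched)
  cycles
}

empty_cycles <- function() {
  tibble::tibble(person_id = integer(), regimen_concept_id = integer(),
                 index_date = as.Date(character()),
                 start_date = as.Date(character()),
                 end_date = as.Date(character()),
                 component_record_ids = list())
}

#' Collapse matched cycles into treatment episodes
#'
#' Per (person, regimen), chronological cycles whose successive
#' start-date gaps stay within the regimen's cycle window form one
#' treatment episode with cycle numbers 1..k; a gap beyond the window
#' starts a new treatment episode and resets the numbering.
#'
#' @param cycles Cycle tibble from [extract_cycles()].
#' @param library A [regimen_library()].
#' @return A list of two tibbles: `treatments` (one row per treatment
#'   episode: `treatment_key`, `person_id`, `regimen_concept_id`,
#'   `start_date`, `end_date`, `n_cycles`) and `cycles` (the input plus
#'   `treatment_key` and `cycle_number`).
#' @export
collapse_to_treatment_episodes <- function(cycles, library) {
  if (nrow(cycles) == 0L) {
    return(list(
      treatments = tibble::tibble(
        treatment_key = integer(), person_id = integer(),
        regimen_concept_id = integer(),
        start_date = as.Date(character()), end_date = as.Date(character()),
        n_cycles = integer()),
      cycles = dplyr::mutate(cycles, treatment_key = integer(),
                             cycle_number = integer())))
  }
  cycles <- cycles[order(cycles$person_id, cycles$regimen_concept_id,
                         cycles$start_date), , drop = FALSE]
  window <- vapply(library$definitions, `[[`, integer(1),
                   "cycle_window_days")
  w <- window[as.character(cycles$regimen_concept_id)]
  same_group <- c(FALSE,
                  cycles$person_id[-1] == head(cycles$person_id, -1) &
                  cycles$regimen_concept_id[-1] ==
                    head(cycles$regimen_concept_id, -1))
  gap <- c(NA_integer_,
           days_between(cycles$start_date[-1],
                        head(cycles$start_date, -1)))
  new_episode <- !same_group | gap > w
  cycles$treatment_key <- cumsum(new_episode)
  cycles$cycle_number <- stats::ave(seq_len(nrow(cycles)),
                                    cycles$treatment_key,
                                    FUN = seq_along)
  treatments <- cycles |>
    dplyr::group_by(.data$treatment_key) |>
    dplyr::summarise(
      person_id = .data$person_id[1],
      regimen_concept_id = .data$regimen_concept_id[1],
      start_date = min(.data$start_date),
      end_date = max(.data$end_date),
      n_cycles = dplyr::n(),
      .groups = "drop")
  ord <- order(cycles$person_id, cycles$start_date,
               cycles$regimen_concept_id)
  list(treatments = treatments, cycles = cycles[ord, , drop = FALSE])
}

#' Assign treatment-line numbers to treatment episodes
#'
#' Per person, episodes are taken in start-date order; the first is
#' line 1, and the line advances whenever the regimen differs from the
#' previous episode's regimen, or the start-date gap from the previous
#' episode's start exceeds the previous regimen's line window. A
#' regimen change always starts a new line, even after a single cycle.
#'
#' @param treatments Treatments tibble from
#'   [collapse_to_treatment_episodes()].
#' @param library A [regimen_library()].
#' @return `treatments` with an integer `line_number` column, sorted by
#'   (person, start date).
#' @export
assign_treatment_lines <- function(treatments, library) {
  if (nrow(treatments) == 0L) {
    treatments$line_number <- integer()
    return(treatments)
  }
  treatments <- treatments[order(treatments$person_id,
                                 treatments$start_date,
                                 treatments$regimen_concept_id), ,
                           drop = FALSE]
  line_window <- vapply(library$definitions, `[[`, integer(1),
                        "line_window_days")
  line <- integer(nrow(treatments))
  for (i in seq_len(nrow(treatments))) {
    if (i == 1L || treatments$person_id[i] != treatments$person_id[i - 1L]) {
      line[i] <- 1L
      next
    }
    prev <- i - 1L
    lw <- line_window[as.character(treatments$regimen_concept_id[prev])]
    changed <- treatments$regimen_concept_id[i] !=
      treatments$regimen_concept_id[prev]
    too_far <- days_between(treatments$start_date[i],
                            treatments$start_date[prev]) > lw
    line[i] <- line[prev] + as.integer(changed || too_far)
  }
  treatments$line_number <- line
  treatments
}

#' End-to-end episode extraction
#'
#' Composes the four algorithm steps and serializes the result to the
#' OMOP oncology-extension EPISODE / EPISODE_EVENT schema. Treatment
#' episode rows carry the line number as `episode_number`; cycle rows
#' carry the cycle number and reference their treatment row via
#' `episode_parent_id`. EPISODE_EVENT links component drug records to
#' cycle rows only (treatment rows are reachable through the parent
#' link; double-linking is avoided).
#'
#' @param bundle A [cdm_bundle()] (ingredient-rolled).
#' @param library A [regimen_library()].
#' @param config A [cdm_config()] supplying episode concept IDs.
#' @param persons Optional person filter.
#' @return A list: `episodes` and `events` (EPISODE / EPISODE_EVENT
#'   tibbles), `treatments` and `cycles` (engine-level tibbles), and
#'   `summary` (row counts plus unmatched-index-date count per regimen).
#' @export
extract_episodes <- function(bundle, library, config = cdm_config(),
                             persons = NULL) {
  cycles <- extract_cycles(bundle, library, persons = persons)
  collapsed <- collapse_to_treatment_episodes(cycles, library)
  treatments <- assign_treatment_lines(collapsed$treatments, library)
  cyc <- collapsed$cycles

  treatments <- treatments[order(treatments$person_id,
                                 treatments$start_date,
                                 treatments$regimen_concept_id), ,
                           drop = FALSE]
  n_tr <- nrow(treatments)
  treatments$episode_id <- seq_len(n_tr)
  cyc <- cyc[order(cyc$person_id, cyc$start_date,
                   cyc$regimen_concept_id), , drop = FALSE]
  cyc$episode_id <- n_tr + seq_len(nrow(cyc))
  cyc$parent_episode_id <-
    treatments$episode_id[match(cyc$treatment_key,
                                treatments$treatment_key)]

  regimen_name <- vapply(library$definitions, `[[`, character(1), "name")
  ep_treat <- tibble::tibble(
    episode_id = treatments$episode_id,
    person_id = treatments$person_id,
    episode_concept_id = config$treatment_episode_concept_id,
    episode_start_date = treatments$start_date,
    episode_end_date = treatments$end_date,
    episode_parent_id = NA_integer_,
    episode_number = treatments$line_number,
    episode_object_concept_id = treatments$regimen_concept_id,
    episode_source_value =
      unname(regimen_name[as.character(treatments$regimen_concept_id)]))
  ep_cycle <- tibble::tibble(
    episode_id = cyc$episode_id,
    person_id = cyc$person_id,
    episode_concept_id = config$cycle_episode_concept_id,
    episode_start_date = cyc$start_date,
    episode_end_date = cyc$end_date,
    episode_parent_id = cyc$parent_episode_id,
    episode_number = cyc$cycle_number,
    episode_object_concept_id = cyc$regimen_concept_id,
    episode_source_value =
      unname(regimen_name[as.character(cyc$regimen_concept_id)]))
  episodes <- dplyr::bind_rows(ep_treat, ep_cycle)
  episodes <- episodes[order(episodes$person_id,
                             episodes$episode_start_date,
                             episodes$episode_id), , drop = FALSE]

  events <- tibble::tibble(
    episode_id = rep(cyc$episode_id,
                     lengths(cyc$component_record_ids)),
    event_id = as.integer(unlist(cyc$component_record_ids)),
    episode_event_field_concept_id = config$drug_event_field_concept_id)
  events <- events[order(events$episode_id, events$event_id), ,
                   drop = FALSE]

  unmatched <- attr(cycles, "unmatched_index_dates")
  summary <- list(
    n_persons = length(unique(episodes$person_id)),
    n_treatment_episodes = n_tr,
    n_cycles = nrow(cyc),
    n_unmatched_index_dates = nrow(unmatched),
    unmatched_by_regimen = if (nrow(unmatched) > 0L)
      dplyr::count(unmatched, .data$regimen_concept_id) else NULL)

  list(episodes = episodes, events = events, treatments = treatments,
       cycles = cyc, summary = summary)
}
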