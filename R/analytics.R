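# Descriptive analytics and validation metrics over extracted episode
# tables: regimen-use trends, cycle-iteration heat-map counts,
# treatment trajectories, neutropenia timing, and agreement metrics
# against a gold standard.
#
# All functions consume plain tibbles (the engine-level `treatments` /
# `cycles` tibbles of extract_episodes(), or tables read back from
# EPISODE.csv) and return tidy tibbles ready for plotting or export.

#' Relative regimen use by calendar year
#'
#' Counts treatment episodes by calendar year of their start date and
#' regimen, and normalizes to proportions within each year (proportions
#' sum to 1 per populated year).
#'
#' @param treatments Treatment-episode tibble with `regimen_concept_id`
#'   and `start_date`.
#' @param year_range Optional length-2 integer restricting the years
#'   reported.
#' @return Tibble (`year`, `regimen_concept_id`, `n`, `proportion`).
#' @export
regimen_share_by_year <- function(treatments, year_range = NULL) {
  if (nrow(treatments) == 0L) {
    return(tibble::tibble(year = integer(), regimen_concept_id = integer(),
                          n = integer(), proportion = numeric()))
  }
  out <- treatments |>
    dplyr::mutate(year = as.integer(format(.data$start_date, "%Y"))) |>
    dplyr::count(.data$year, .data$regimen_concept_id) |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  if (!is.null(year_range)) {
    out <- dplyr::filter(out, .data$year >= year_range[1],
                         .data$year <= year_range[2])
  }
  dplyr::arrange(out, .data$year, .data$regimen_concept_id)
}

#' Patient counts by regimen and iterated cycle count
#'
#' For each patient's first treatment episode per regimen, counts
#' patients by (regimen, number of cycles completed); cells below
#' `min_cell` patients are suppressed (count masked to `NA`), matching
#' small-cell reporting rules for privacy.
#'
#' @param treatments Treatment-episode tibble with `person_id`,
#'   `regimen_concept_id`, `start_date`, `n_cycles`.
#' @param min_cell Minimum reportable cell size (default 10).
#' @return Tibble (`regimen_concept_id`, `n_cycles`, `n_patients`,
#'   `suppressed`); suppressed rows keep `NA` in `n_patients`.
#' @export
cycle_iteration_matrix <- function(treatments, min_cell = 10L) {
  if (nrow(treatments) == 0L) {
    return(tibble::tibble(regimen_concept_id = integer(),
                          n_cycles = integer(), n_patients = integer(),
                          suppressed = logical()))
  }
  first_course <- treatments |>
    dplyr::arrange(.data$person_id, .data$start_date) |>
    dplyr::group_by(.data$person_id, .data$regimen_concept_id) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  first_course |>
    dplyr::count(.data$regimen_concept_id, .data$n_cycles,
                 name = "n_patients") |>
    dplyr::mutate(suppressed = .data$n_patients < min_cell,
                  n_patients = ifelse(.data$suppressed, NA_integer_,
                                      .data$n_patients)) |>
    dplyr::arrange(.data$regimen_concept_id, .data$n_cycles)
}

#' Build treatment-trajectory nodes and edges
#'
#' Per person, the treatment path is the chronological sequence of
#' treatment elements: surgery and radiation procedures (via their
#' category) interleaved with treatment episodes (labelled by regimen);
#' consecutive identical labels are merged (a regimen change or a
#' transition between treatment types is a step along the trajectory).
#' Paths are truncated at `max_depth` elements; nodes are aggregated by
#' (depth, label); nodes with fewer than `min_node_count` patients are
#' removed together with their outgoing edges; percentages are computed
#' within each depth among reported nodes' patients.
#'
#' @param treatments Treatment-episode tibble (`person_id`,
#'   `regimen_concept_id`, `start_date`) with optional
#'   `episode_source_value` used as the label (falls back to the
#'   concept ID).
#' @param procedures Procedure tibble (`person_id`, `procedure_date`,
#'   `category`); only SURGERY / RADIATION rows become path elements.
#' @param max_depth Truncation depth (e.g. 3 or 4).
#' @param min_node_count Suppression threshold (e.g. 10 or 5).
#' @param group_by_first_treatment When `TRUE`, adds the first path
#'   element's label as a `first_treatment` column on nodes and edges so
#'   trajectories can be displayed per first-line treatment type.
#' @return List of tibbles `nodes` (`depth`, `label`, `n_patients`,
#'   `percent_of_depth`[, `first_treatment`]) and `edges`
#'   (`from_depth`, `from_label`, `to_label`, `n_patients`
#'   [, `first_treatment`]).
#' @export
build_trajectories <- function(treatments, procedures = NULL,
                               max_depth = 3L, min_node_count = 10L,
                               group_by_first_treatment = FALSE) {
  label_col <- if ("episode_source_value" %in% names(treatments)) {
    treatments$episode_source_value
  } else {
    as.character(treatments$regimen_concept_id)
  }
  elements <- tibble::tibble(person_id = treatments$person_id,
                             date = treatments$start_date,
                             label = label_col)
  if (!is.null(procedures) && nrow(procedures) > 0L) {
    pr <- procedures[procedures$category %in% c("SURGERY", "RADIATION"), ,
                     drop = FALSE]
    if (nrow(pr) > 0L) {
      elements <- dplyr::bind_rows(elements, tibble::tibble(
        person_id = pr$person_id, date = pr$procedure_date,
        label = pr$category))
    }
  }
  if (nrow(elements) == 0L) {
    nodes <- tibble::tibble(depth = integer(), label = character(),
                            n_patients = integer(),
                            percent_of_depth = numeric())
    edges <- tibble::tibble(from_depth = integer(),
                            from_label = character(),
                            to_label = character(), n_patients = integer())
    return(list(nodes = nodes, edges = edges))
  }
  paths <- elements |>
    dplyr::arrange(.data$person_id, .data$date) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::filter(.data$label != dplyr::lag(.data$label,
                                            default = "")) |>
    dplyr::mutate(depth = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$depth <= max_depth)
  if (group_by_first_treatment) {
    firsts <- paths |>
      dplyr::filter(.data$depth == 1L) |>
      dplyr::select("person_id", first_treatment = "label")
    paths <- dplyr::left_join(paths, firsts, by = "person_id")
  }
  group_cols <- c(if (group_by_first_treatment) "first_treatment",
                  "depth", "label")
  nodes <- paths |>
    dplyr::count(dplyr::across(dplyr::all_of(group_cols)),
                 name = "n_patients") |>
    dplyr::filter(.data$n_patients >= min_node_count)
  pct_cols <- setdiff(group_cols, "label")
  nodes <- nodes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(pct_cols))) |>
    dplyr::mutate(percent_of_depth = 100 * .data$n_patients /
                    sum(.data$n_patients)) |>
    dplyr::ungroup()

  edges_raw <- paths |>
    dplyr::group_by(.data$person_id) |>
    dplyr::arrange(.data$depth, .by_group = TRUE) |>
    dplyr::mutate(to_label = dplyr::lead(.data$label)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$to_label))
  edge_cols <- c(if (group_by_first_treatment) "first_treatment",
                 "depth", "label", "to_label")
  edges <- edges_raw |>
    dplyr::count(dplyr::across(dplyr::all_of(edge_cols)),
                 name = "n_patients") |>
    dplyr::rename(from_depth = "depth", from_label = "label")
  # drop edges touching suppressed nodes
  node_key <- paste(nodes$depth, nodes$label,
                    if (group_by_first_treatment) nodes$first_treatment)
  keep <- paste(edges$from_depth, edges$from_label,
                if (group_by_first_treatment) edges$first_treatment) %in%
    node_key &
    paste(edges$from_depth + 1L, edges$to_label,
          if (group_by_first_treatment) edges$first_treatment) %in%
    node_key
  edges <- edges[keep, , drop = FALSE]
  list(nodes = dplyr::arrange(nodes, dplyr::across(dplyr::all_of(group_cols))),
       edges = dplyr::arrange(edges,
                              dplyr::across(dplyr::all_of(
                                c(if (group_by_first_treatment)
                                  "first_treatment",
                                  "from_depth", "from_label",
                                  "to_label")))))
}

#' Detect chemotherapy-induced neutropenia and febrile neutropenia
#'
#' Scans ANC measurements for candidate events:
#' * `CIN_G4` - ANC below `0.5 x 10^9`/L (CTCAE v5.0 grade 4);
#' * `FN` - ANC below `1.0 x 10^9`/L accompanied by a fever/infection
#'   diagnosis on the same day or a G-CSF exposure starting within
#'   `gcsf_lookahead_days` after the measurement.
#'
#' Measurements dated inside any chemotherapy administration span
#' `[start_date, end_date]` are ignored: on an administration day the
#' ANC may be transiently lowered.
#'
#' @param measurements Measurement tibble with ANC normalized to
#'   `10^9`/L (see [normalize_anc_units()]).
#' @param conditions Condition tibble (fever/infection diagnoses).
#' @param chemo_exposures Drug-exposure tibble of chemotherapy records
#'   (administration spans; G-CSF rows, if present, are not treated as
#'   chemotherapy).
#' @param config A [cdm_config()] naming the concept sets.
#' @param cin_threshold,fn_threshold Thresholds in `10^9`/L.
#' @param gcsf_lookahead_days Days after a low ANC in which a G-CSF
#'   exposure qualifies the event as FN (default 3).
#' @return Tibble of candidate events (`person_id`, `event_date`,
#'   `event_type`, `anc_value`), one row per (measurement, type met),
#'   sorted by person and date.
#' @export
detect_cin_fn_events <- function(measurements, conditions,
                                 chemo_exposures,
                                 config = cdm_config(),
                                 cin_threshold = 0.5, fn_threshold = 1.0,
                                 gcsf_lookahead_days = 3L) {
  anc <- measurements[measurements$measurement_concept_id %in%
                        config$anc_concepts &
                        !is.na(measurements$value), , drop = FALSE]
  empty <- tibble::tibble(person_id = integer(),
                          event_date = as.Date(character()),
                          event_type = character(), anc_value = numeric())
  if (nrow(anc) == 0L) return(empty)

  gcsf <- chemo_exposures[chemo_exposures$ingredient_concept_id %in%
                            config$gcsf_concepts, , drop = FALSE]
  chemo <- chemo_exposures[!(chemo_exposures$ingredient_concept_id %in%
                               config$gcsf_concepts), , drop = FALSE]
  fever <- conditions[conditions$condition_concept_id %in%
                        config$fever_infection_concepts, , drop = FALSE]

  out <- list()
  chemo_by_person <- split(chemo, chemo$person_id)
  fever_by_person <- split(fever$condition_date, fever$person_id)
  gcsf_by_person <- split(gcsf$start_date, gcsf$person_id)
  for (p in split(anc, anc$person_id)) {
    pid <- as.character(p$person_id[1])
    spans <- chemo_by_person[[pid]]
    if (!is.null(spans) && nrow(spans) > 0L) {
      on_admin <- vapply(p$measurement_date, function(d)
        any(d >= spans$start_date & d <= spans$end_date), logical(1))
      p <- p[!on_admin, , drop = FALSE]
    }
    if (nrow(p) == 0L) next
    fdates <- fever_by_person[[pid]]
    gdates <- gcsf_by_person[[pid]]
    is_cin <- p$value < cin_threshold
    has_fever <- if (is.null(fdates)) rep(FALSE, nrow(p)) else
      p$measurement_date %in% fdates
    has_gcsf <- if (is.null(gdates)) rep(FALSE, nrow(p)) else
      vapply(p$measurement_date, function(d)
        any(gdates >= d & gdates <= d + gcsf_lookahead_days), logical(1))
    is_fn <- p$value < fn_threshold & (has_fever | has_gcsf)
    if (any(is_cin)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        person_id = p$person_id[is_cin],
        event_date = p$measurement_date[is_cin],
        event_type = "CIN_G4", anc_value = p$value[is_cin])
    }
    if (any(is_fn)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        person_id = p$person_id[is_fn],
        event_date = p$measurement_date[is_fn],
        event_type = "FN", anc_value = p$value[is_fn])
    }
  }
  if (length(out) == 0L) return(empty)
  dplyr::arrange(dplyr::bind_rows(out), .data$person_id,
                 .data$event_date, .data$event_type)
}

onset_bins <- function() {
  tibble::tibble(lo = c(2L, 9L, 16L, 23L), hi = c(8L, 15L, 22L, 29L),
                 bin_label = c("2-8", "9-15", "16-22", "23-29"))
}

bin_gap_days <- function(gap) {
  bins <- onset_bins()
  idx <- findInterval(gap, bins$lo)
  ok <- idx >= 1L & gap <= bins$hi[pmax(idx, 1L)]
  out <- rep(NA_character_, length(gap))
  out[ok] <- bins$bin_label[idx[ok]]
  out
}

#' Timing of first neutropenia onset per patient
#'
#' For each patient with a first-line treatment episode, takes the
#' first detected CIN/FN event, computes the gap in days from the first
#' first-line chemotherapy start, keeps events within `horizon_days`,
#' and labels 7-day onset bins ("2-8", "9-15", "16-22", "23-29"). Gaps
#' of 0-1 days are administration-proximal and excluded.
#'
#' @param events Event tibble from [detect_cin_fn_events()].
#' @param first_line_treatments Treatment-episode tibble restricted to
#'   `line_number == 1` (columns `person_id`, `regimen_concept_id`,
#'   `start_date`).
#' @param horizon_days Only events within this many days of
#'   chemotherapy initiation count (default 30).
#' @return Tibble (`person_id`, `regimen_concept_id`, `event_date`,
#'   `event_type`, `gap_days`, `bin_label`), one row per patient with a
#'   qualifying event.
#' @export
onset_timing <- function(events, first_line_treatments,
                         horizon_days = 30L) {
  empty <- tibble::tibble(person_id = integer(),
                          regimen_concept_id = integer(),
                          event_date = as.Date(character()),
                          event_type = character(), gap_days = integer(),
                          bin_label = character())
  if (nrow(events) == 0L || nrow(first_line_treatments) == 0L) {
    return(empty)
  }
  fl <- first_line_treatments |>
    dplyr::arrange(.data$person_id, .data$start_date) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("person_id", "regimen_concept_id",
                  first_start = "start_date")
  out <- events |>
    dplyr::inner_join(fl, by = "person_id") |>
    dplyr::mutate(gap_days = as.integer(.data$event_date -
                                          .data$first_start)) |>
    dplyr::filter(.data$gap_days >= 2L,
                  .data$gap_days <= horizon_days) |>
    dplyr::arrange(.data$person_id, .data$event_date,
                   .data$event_type) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::mutate(bin_label = bin_gap_days(.data$gap_days)) |>
    dplyr::select("person_id", "regimen_concept_id", "event_date",
                  "event_type", "gap_days", "bin_label")
  out
}

#' Per-cycle incidence of neutropenia events for top regimens
#'
#' Attributes each event to the cycle whose interval
#' `[cycle start, next cycle start)` (last cycle: through the cycle
#' window) contains the event date, then computes, per (regimen, cycle
#' number), the fraction of patients reaching that cycle who had at
#' least one event in it. Regimens are ranked by total event frequency
#' and the top `top_k_regimens` kept.
#'
#' @param events Event tibble from [detect_cin_fn_events()].
#' @param cycles Cycle tibble (`person_id`, `regimen_concept_id`,
#'   `cycle_number`, `start_date`) from [extract_episodes()].
#' @param library A [regimen_library()] (for the last cycle's window).
#' @param top_k_regimens Number of regimens to keep (default 4).
#' @return Tibble (`regimen_concept_id`, `cycle_number`, `n_at_risk`,
#'   `n_events`, `incidence`).
#' @export
incidence_per_cycle <- function(events, cycles,
                                library = builtin_regimen_library(),
                                top_k_regimens = 4L) {
  empty <- tibble::tibble(regimen_concept_id = integer(),
                          cycle_number = integer(), n_at_risk = integer(),
                          n_events = integer(), incidence = numeric())
  if (nrow(cycles) == 0L) return(empty)
  window <- vapply(library$definitions, `[[`, integer(1),
                   "cycle_window_days")
  cyc <- cycles |>
    dplyr::arrange(.data$person_id, .data$regimen_concept_id,
                   .data$start_date) |>
    dplyr::group_by(.data$person_id, .data$regimen_concept_id) |>
    dplyr::mutate(next_start = dplyr::lead(.data$start_date)) |>
    dplyr::ungroup() |>
    dplyr::mutate(interval_end = dplyr::coalesce(
      .data$next_start - 1L,
      .data$start_date +
        unname(window[as.character(.data$regimen_concept_id)]) - 1L))

  ev_cyc <- empty
  if (nrow(events) > 0L) {
    ev_cyc <- events |>
      dplyr::distinct(.data$person_id, .data$event_date) |>
      dplyr::inner_join(cyc, by = "person_id",
                        relationship = "many-to-many") |>
      dplyr::filter(.data$event_date >= .data$start_date,
                    .data$event_date <= .data$interval_end) |>
      dplyr::distinct(.data$person_id, .data$regimen_concept_id,
                      .data$cycle_number)
  }
  at_risk <- cyc |>
    dplyr::distinct(.data$person_id, .data$regimen_concept_id,
                    .data$cycle_number) |>
    dplyr::count(.data$regimen_concept_id, .data$cycle_number,
                 name = "n_at_risk")
  counts <- if (nrow(ev_cyc) > 0L) {
    dplyr::count(ev_cyc, .data$regimen_concept_id, .data$cycle_number,
                 name = "n_events")
  } else {
    tibble::tibble(regimen_concept_id = integer(),
                   cycle_number = integer(), n_events = integer())
  }
  out <- at_risk |>
    dplyr::left_join(counts,
                     by = c("regimen_concept_id", "cycle_number")) |>
    dplyr::mutate(n_events = dplyr::coalesce(.data$n_events, 0L),
                  incidence = .data$n_events / .data$n_at_risk)
  totals <- out |>
    dplyr::group_by(.data$regimen_concept_id) |>
    dplyr::summarise(total_events = sum(.data$n_events),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total_events),
                   .data$regimen_concept_id)
  keep <- head(totals$regimen_concept_id, top_k_regimens)
  out |>
    dplyr::filter(.data$regimen_concept_id %in% keep) |>
    dplyr::arrange(.data$regimen_concept_id, .data$cycle_number)
}

#' Agreement metrics against a gold standard
#'
#' Compares algorithm-assigned regimen labels and cycle counts with a
#' per-person gold standard:
#' * PPV: fraction of evaluable persons whose predicted regimen matches
#'   the gold regimen;
#' * cycle-count accuracy: among regimen-matched persons, fraction with
#'   an exact cycle-count match;
#' * MAE / RMSE of the cycle-count differences among regimen-matched
#'   persons.
#'
#' Persons whose gold regimen is unknown ("without information") are
#' excluded from the denominators and reported separately.
#'
#' @param predicted Tibble (`person_id`, `regimen_concept_id`,
#'   `n_cycles`), one row per evaluated person (e.g. the first
#'   treatment episode). Strata are defined by the predicted regimen,
#'   mirroring chart-review designs that sample cases per
#'   algorithm-derived regimen.
#' @param gold Tibble (`person_id`, `regimen_concept_id`, `n_cycles`);
#'   `NA` regimen means the gold source carried no information for that
#'   person.
#' @param by_regimen When `TRUE` (default) metrics are computed per
#'   predicted regimen; a pooled row with `regimen_concept_id = NA` is
#'   always appended.
#' @return Tibble (`regimen_concept_id`, `n_without_information`,
#'   `n_evaluable`, `n_regimen_matched`, `ppv`, `n_cycle_matched`,
#'   `cycle_accuracy`, `mae`, `rmse`); `ppv` and `cycle_accuracy` are
#'   percentages. Metrics are `NA` when a denominator is zero.
#' @export
validation_metrics <- function(predicted, gold, by_regimen = TRUE) {
  stopifnot(all(c("person_id", "regimen_concept_id", "n_cycles") %in%
                  names(predicted)),
            all(c("person_id", "regimen_concept_id", "n_cycles") %in%
                  names(gold)))
  joined <- dplyr::left_join(
    predicted, gold, by = "person_id", suffix = c("_pred", "_gold"))
  one_stratum <- function(df, id) {
    without_info <- is.na(df$regimen_concept_id_gold)
    df <- df[!without_info, , drop = FALSE]
    matched <- df$regimen_concept_id_pred == df$regimen_concept_id_gold
    n_eval <- nrow(df)
    n_match <- sum(matched)
    diffs <- df$n_cycles_pred[matched] - df$n_cycles_gold[matched]
    tibble::tibble(
      regimen_concept_id = id,
      n_without_information = sum(without_info),
      n_evaluable = n_eval,
      n_regimen_matched = n_match,
      ppv = if (n_eval > 0L) 100 * n_match / n_eval else NA_real_,
      n_cycle_matched = sum(diffs == 0L),
      cycle_accuracy = if (n_match > 0L)
        100 * sum(diffs == 0L) / n_match else NA_real_,
      mae = if (n_match > 0L) mean(abs(diffs)) else NA_real_,
      rmse = if (n_match > 0L) sqrt(mean(diffs^2)) else NA_real_)
  }
  if (nrow(joined) == 0L) {
    warning("validation_metrics: no persons to evaluate", call. = FALSE)
  }
  rows <- list()
  if (by_regimen && nrow(joined) > 0L) {
    for (g in sort(unique(joined$regimen_concept_id_pred))) {
      sub <- joined[joined$regimen_concept_id_pred == g, , drop = FALSE]
      rows[[length(rows) + 1L]] <- one_stratum(sub, g)
    }
  }
  rows[[length(rows) + 1L]] <- one_stratum(joined, NA_integer_)
  dplyr::bind_rows(rows)
}
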