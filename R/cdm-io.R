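# Minimal OMOP-CDM v5.3 I/O: read the handful of tables the matcher and
# analytics need, roll drug concepts up to ingredients, and write the
# oncology-extension EPISODE / EPISODE_EVENT output.
#
# Files are RFC 4180 CSV, UTF-8, header row mandatory, dates ISO-8601.
# Only *_date columns are used; *_datetime precision is out of scope
# because the matcher operates on dispense dates.

#' Concept configuration for CDM I/O and analytics
#'
#' Collects the concept IDs that the OMOP standard does not pin down for
#' this workflow (or that the built-in synthetic vocabulary supplies).
#' `cycle_episode_concept_id` / `treatment_episode_concept_id` default to
#' the oncology-extension "Treatment Cycle" (32532) and "Treatment
#' Regimen" (32531) episode concepts; `drug_event_field_concept_id`
#' identifies the `drug_exposure.drug_exposure_id` field in
#' EPISODE_EVENT rows. The remaining sets are the synthetic fixture
#' concepts of the cohort simulator; site deployments override them with
#' their local concept sets.
#'
#' @param cycle_episode_concept_id Episode concept for one treatment
#'   cycle.
#' @param treatment_episode_concept_id Episode concept for a collapsed
#'   treatment episode (one regimen course).
#' @param drug_event_field_concept_id Field concept linking an
#'   EPISODE_EVENT row to `drug_exposure.drug_exposure_id`.
#' @param anc_concepts Measurement concepts holding absolute neutrophil
#'   counts.
#' @param fever_infection_concepts Condition concepts meaning fever or
#'   infection (febrile-neutropenia qualifier).
#' @param gcsf_concepts Ingredient concepts for granulocyte
#'   colony-stimulating factors.
#' @param surgery_concepts,radiation_concepts Procedure concepts mapped
#'   to the SURGERY / RADIATION trajectory categories.
#' @return A list of class `cdm_config`.
#' @export
cdm_config <- function(cycle_episode_concept_id = 32532L,
                       treatment_episode_concept_id = 32531L,
                       drug_event_field_concept_id = 1147094L,
                       anc_concepts = 3001L,
                       fever_infection_concepts = c(4001L, 4002L),
                       gcsf_concepts = 1020L,
                       surgery_concepts = c(5001L, 5002L, 5003L),
                       radiation_concepts = 5100L) {
  structure(list(
    cycle_episode_concept_id = as.integer(cycle_episode_concept_id),
    treatment_episode_concept_id = as.integer(treatment_episode_concept_id),
    drug_event_field_concept_id = as.integer(drug_event_field_concept_id),
    anc_concepts = as.integer(anc_concepts),
    fever_infection_concepts = as.integer(fever_infection_concepts),
    gcsf_concepts = as.integer(gcsf_concepts),
    surgery_concepts = as.integer(surgery_concepts),
    radiation_concepts = as.integer(radiation_concepts)
  ), class = "cdm_config")
}

empty_drug_exposure <- function() {
  tibble::tibble(record_id = integer(), person_id = integer(),
                 drug_concept_id = integer(),
                 ingredient_concept_id = integer(),
                 start_date = as.Date(character()),
                 end_date = as.Date(character()))
}

empty_measurement <- function() {
  tibble::tibble(person_id = integer(), measurement_concept_id = integer(),
                 measurement_date = as.Date(character()),
                 value = numeric(), unit = character())
}

empty_condition <- function() {
  tibble::tibble(person_id = integer(), condition_concept_id = integer(),
                 condition_date = as.Date(character()))
}

empty_procedure <- function() {
  tibble::tibble(person_id = integer(), procedure_concept_id = integer(),
                 procedure_date = as.Date(character()),
                 category = character())
}

empty_concept_ancestor <- function() {
  tibble::tibble(descendant_concept_id = integer(),
                 ancestor_concept_id = integer())
}

#' Assemble an in-memory CDM bundle
#'
#' The bundle is the common input container for the episode engine and
#' the analytics: one tibble per source table, already typed and
#' date-parsed. [read_cdm_tables()] builds one from CSV files; the
#' cohort simulator builds one directly.
#'
#' @param drug_exposure Tibble with columns `record_id`, `person_id`,
#'   `drug_concept_id`, `ingredient_concept_id`, `start_date`,
#'   `end_date`.
#' @param measurement,condition,procedure,concept_ancestor Optional
#'   companion tibbles (empty prototypes by default).
#' @return A list of class `cdm_bundle`.
#' @export
cdm_bundle <- function(drug_exposure = empty_drug_exposure(),
                       measurement = empty_measurement(),
                       condition = empty_condition(),
                       procedure = empty_procedure(),
                       concept_ancestor = empty_concept_ancestor()) {
  drug_exposure <- tibble::as_tibble(drug_exposure)
  if (!"ingredient_concept_id" %in% names(drug_exposure)) {
    drug_exposure$ingredient_concept_id <- drug_exposure$drug_concept_id
  }
  stopifnot(
    all(c("record_id", "person_id", "drug_concept_id", "start_date",
          "end_date") %in% names(drug_exposure)),
    !anyDuplicated(drug_exposure$record_id)
  )
  if (any(drug_exposure$end_date < drug_exposure$start_date)) {
    stop("drug_exposure: end_date before start_date", call. = FALSE)
  }
  drug_exposure <- drug_exposure[, c("record_id", "person_id",
                                     "drug_concept_id",
                                     "ingredient_concept_id",
                                     "start_date", "end_date")]
  structure(list(
    drug_exposure = drug_exposure,
    measurement = tibble::as_tibble(measurement),
    condition = tibble::as_tibble(condition),
    procedure = tibble::as_tibble(procedure),
    concept_ancestor = tibble::as_tibble(concept_ancestor)
  ), class = "cdm_bundle")
}

#' @export
print.cdm_bundle <- function(x, ...) {
  cat("<cdm_bundle>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-17s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

read_csv_checked <- function(path, required, col_types) {
  # missing-column diagnostics are ours (below), not readr's
  df <- withCallingHandlers(
    readr::read_csv(path, col_types = col_types,
                    show_col_types = FALSE, progress = FALSE),
    warning = function(w) {
      if (grepl("don't match the column names", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

drop_bad_dates <- function(df, cols, table_name) {
  bad <- rep(FALSE, nrow(df))
  for (col in cols) bad <- bad | is.na(df[[col]])
  if (any(bad)) {
    message(sprintf("%s: dropped %d row(s) with unparseable %s",
                    table_name, sum(bad), paste(cols, collapse = "/")))
  }
  df[!bad, , drop = FALSE]
}

#' Read OMOP-CDM shaped tables from a directory
#'
#' Expects `DRUG_EXPOSURE.csv` (mandatory) and, when present,
#' `MEASUREMENT.csv`, `CONDITION_OCCURRENCE.csv`,
#' `PROCEDURE_OCCURRENCE.csv` and `CONCEPT_ANCESTOR.csv`, with standard
#' OMOP v5.3 column names. Missing drug exposure end dates are imputed
#' to the start date (logged); rows with unparseable dates are dropped
#' (logged). ANC measurement values are normalized to `10^9` cells/L via
#' [normalize_anc_units()]. Procedure rows are categorized as
#' SURGERY / RADIATION / OTHER via the `config` concept sets.
#'
#' @param directory Path containing the CSV files.
#' @param config A [cdm_config()].
#' @return A [cdm_bundle()]; drug concepts are not yet rolled up to
#'   ingredients (see [rollup_to_ingredients()]).
#' @export
read_cdm_tables <- function(directory, config = cdm_config()) {
  stopifnot(dir.exists(directory))
  path <- function(f) file.path(directory, f)
  if (!file.exists(path("DRUG_EXPOSURE.csv"))) {
    stop("missing required file DRUG_EXPOSURE.csv in ", directory,
         call. = FALSE)
  }

  de <- read_csv_checked(
    path("DRUG_EXPOSURE.csv"),
    required = c("drug_exposure_id", "person_id", "drug_concept_id",
                 "drug_exposure_start_date"),
    col_types = readr::cols(
      drug_exposure_id = readr::col_integer(),
      person_id = readr::col_integer(),
      drug_concept_id = readr::col_integer(),
      drug_exposure_start_date = readr::col_date(),
      drug_exposure_end_date = readr::col_date(),
      .default = readr::col_guess()))
  de <- drop_bad_dates(de, "drug_exposure_start_date", "DRUG_EXPOSURE")
  if (!"drug_exposure_end_date" %in% names(de)) {
    de$drug_exposure_end_date <- as.Date(NA)
  }
  n_imputed <- sum(is.na(de$drug_exposure_end_date))
  if (n_imputed > 0L) {
    message(sprintf(
      "DRUG_EXPOSURE: imputed %d missing end date(s) to the start date",
      n_imputed))
    de$drug_exposure_end_date[is.na(de$drug_exposure_end_date)] <-
      de$drug_exposure_start_date[is.na(de$drug_exposure_end_date)]
  }
  drug_exposure <- tibble::tibble(
    record_id = de$drug_exposure_id,
    person_id = de$person_id,
    drug_concept_id = de$drug_concept_id,
    ingredient_concept_id = de$drug_concept_id,
    start_date = de$drug_exposure_start_date,
    end_date = de$drug_exposure_end_date)

  measurement <- empty_measurement()
  if (file.exists(path("MEASUREMENT.csv"))) {
    me <- read_csv_checked(
      path("MEASUREMENT.csv"),
      required = c("person_id", "measurement_concept_id",
                   "measurement_date", "value_as_number"),
      col_types = readr::cols(
        person_id = readr::col_integer(),
        measurement_concept_id = readr::col_integer(),
        measurement_date = readr::col_date(),
        value_as_number = readr::col_double(),
        unit_source_value = readr::col_character(),
        .default = readr::col_guess()))
    me <- drop_bad_dates(me, "measurement_date", "MEASUREMENT")
    measurement <- tibble::tibble(
      person_id = me$person_id,
      measurement_concept_id = me$measurement_concept_id,
      measurement_date = me$measurement_date,
      value = me$value_as_number,
      unit = if ("unit_source_value" %in% names(me))
        me$unit_source_value else NA_character_)
    measurement <- normalize_anc_units(measurement, config)
  }

  condition <- empty_condition()
  if (file.exists(path("CONDITION_OCCURRENCE.csv"))) {
    co <- read_csv_checked(
      path("CONDITION_OCCURRENCE.csv"),
      required = c("person_id", "condition_concept_id",
                   "condition_start_date"),
      col_types = readr::cols(
        person_id = readr::col_integer(),
        condition_concept_id = readr::col_integer(),
        condition_start_date = readr::col_date(),
        .default = readr::col_guess()))
    co <- drop_bad_dates(co, "condition_start_date", "CONDITION_OCCURRENCE")
    condition <- tibble::tibble(
      person_id = co$person_id,
      condition_concept_id = co$condition_concept_id,
      condition_date = co$condition_start_date)
  }

  procedure <- empty_procedure()
  if (file.exists(path("PROCEDURE_OCCURRENCE.csv"))) {
    po <- read_csv_checked(
      path("PROCEDURE_OCCURRENCE.csv"),
      required = c("person_id", "procedure_concept_id", "procedure_date"),
      col_types = readr::cols(
        person_id = readr::col_integer(),
        procedure_concept_id = readr::col_integer(),
        procedure_date = readr::col_date(),
        .default = readr::col_guess()))
    po <- drop_bad_dates(po, "procedure_date", "PROCEDURE_OCCURRENCE")
    procedure <- tibble::tibble(
      person_id = po$person_id,
      procedure_concept_id = po$procedure_concept_id,
      procedure_date = po$procedure_date,
      category = categorize_procedures(po$procedure_concept_id, config))
  }

  concept_ancestor <- empty_concept_ancestor()
  if (file.exists(path("CONCEPT_ANCESTOR.csv"))) {
    ca <- read_csv_checked(
      path("CONCEPT_ANCESTOR.csv"),
      required = c("descendant_concept_id", "ancestor_concept_id"),
      col_types = readr::cols(
        descendant_concept_id = readr::col_integer(),
        ancestor_concept_id = readr::col_integer(),
        .default = readr::col_guess()))
    concept_ancestor <- ca[, c("descendant_concept_id",
                               "ancestor_concept_id")]
  }

  cdm_bundle(drug_exposure = drug_exposure, measurement = measurement,
             condition = condition, procedure = procedure,
             concept_ancestor = concept_ancestor)
}

#' Map procedure concepts to trajectory categories
#' @noRd
categorize_procedures <- function(concept_ids, config = cdm_config()) {
  dplyr::case_when(
    concept_ids %in% config$surgery_concepts ~ "SURGERY",
    concept_ids %in% config$radiation_concepts ~ "RADIATION",
    TRUE ~ "OTHER")
}

#' Normalize absolute neutrophil counts to 10^9 cells/L
#'
#' Laboratory systems report ANC either in cells per microlitre
#' (thousands, e.g. 5582) or in `10^9` cells/L (e.g. 5.582). Rows whose
#' measurement concept is in `config$anc_concepts` are rescaled by
#' 1/1000 when the unit string denotes cells/uL or, unit absent, when
#' the value exceeds 100 (no plausible ANC exceeds `100 x 10^9`/L).
#' Each normalization batch is logged.
#'
#' @param measurement Measurement tibble (see [cdm_bundle()]).
#' @param config A [cdm_config()].
#' @return The measurement tibble with normalized `value`s and unit set
#'   to `"10^9/L"` for rescaled rows.
#' @export
normalize_anc_units <- function(measurement, config = cdm_config()) {
  if (nrow(measurement) == 0L) return(measurement)
  is_anc <- measurement$measurement_concept_id %in% config$anc_concepts
  unit <- tolower(measurement$unit %||% NA_character_)
  per_ul <- !is.na(unit) & grepl("ul|uL|mm3|mcl|microlit", unit,
                                 ignore.case = TRUE)
  heuristic <- is.na(unit) & !is.na(measurement$value) &
    measurement$value > 100
  rescale <- is_anc & (per_ul | heuristic)
  if (any(rescale)) {
    message(sprintf(
      "MEASUREMENT: normalized %d ANC value(s) from cells/uL to 10^9/L",
      sum(rescale)))
    measurement$value[rescale] <- measurement$value[rescale] / 1000
    measurement$unit[rescale] <- "10^9/L"
  }
  if (any(is_anc & !is.na(measurement$value) & measurement$value < 0)) {
    stop("negative ANC value after normalization", call. = FALSE)
  }
  measurement
}

#' Roll drug concepts up to ingredient concepts
#'
#' Knowledge-base drug roles are stated at ingredient level, so branded
#' or clinical drug concepts in DRUG_EXPOSURE must be mapped to their
#' single ingredient ancestor before matching. The supplied
#' `concept_ancestor` table must be restricted to ingredient ancestors.
#' Unmapped concepts pass through unchanged with a warning (they simply
#' never match a knowledge-base role unless the KB lists them verbatim);
#' a drug concept with more than one ingredient ancestor (combination
#' product) is an error, as multi-ingredient products are out of scope.
#'
#' @param exposures Drug-exposure tibble (see [cdm_bundle()]).
#' @param concept_ancestor Tibble with `descendant_concept_id`,
#'   `ancestor_concept_id`.
#' @return `exposures` with `ingredient_concept_id` filled in.
#' @export
rollup_to_ingredients <- function(exposures, concept_ancestor) {
  if (nrow(concept_ancestor) == 0L) {
    exposures$ingredient_concept_id <- exposures$drug_concept_id
    return(exposures)
  }
  multi <- concept_ancestor |>
    dplyr::distinct(.data$descendant_concept_id, .data$ancestor_concept_id) |>
    dplyr::count(.data$descendant_concept_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi) > 0L) {
    stop("drug concept(s) mapping to more than one ingredient: ",
         paste(multi$descendant_concept_id, collapse = ", "),
         " (multi-ingredient products are out of scope)", call. = FALSE)
  }
  map <- setNames(concept_ancestor$ancestor_concept_id,
                  as.character(concept_ancestor$descendant_concept_id))
  mapped <- unname(map[as.character(exposures$drug_concept_id)])
  unmapped <- is.na(mapped)
  if (any(unmapped)) {
    warning(sprintf(
      "%d exposure(s) with drug concept(s) not in CONCEPT_ANCESTOR kept as their own ingredient",
      sum(unmapped)), call. = FALSE)
  }
  exposures$ingredient_concept_id <-
    as.integer(ifelse(unmapped, exposures$drug_concept_id, mapped))
  exposures
}

episode_columns <- c("episode_id", "person_id", "episode_concept_id",
                     "episode_start_date", "episode_end_date",
                     "episode_parent_id", "episode_number",
                     "episode_object_concept_id", "episode_source_value")
episode_event_columns <- c("episode_id", "event_id",
                           "episode_event_field_concept_id")

check_episode_tables <- function(episodes, events) {
  stopifnot(all(episode_columns %in% names(episodes)),
            all(episode_event_columns %in% names(events)))
  child <- episodes[!is.na(episodes$episode_parent_id), , drop = FALSE]
  if (nrow(child) > 0L) {
    parent_idx <- match(child$episode_parent_id, episodes$episode_id)
    if (anyNA(parent_idx)) {
      stop("EPISODE: dangling episode_parent_id reference", call. = FALSE)
    }
    ok <- episodes$episode_start_date[parent_idx] <= child$episode_start_date &
      episodes$episode_end_date[parent_idx] >= child$episode_end_date
    if (!all(ok)) {
      stop("EPISODE: parent episode dates do not bound child dates",
           call. = FALSE)
    }
  }
  if (nrow(events) > 0L && !all(events$episode_id %in% episodes$episode_id)) {
    stop("EPISODE_EVENT: dangling episode_id reference", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write EPISODE / EPISODE_EVENT tables
#'
#' Emits the OMOP oncology-extension output as two CSV files with fixed
#' column order and deterministic row order
#' (`person_id`, `episode_start_date`, `episode_id` for episodes;
#' `episode_id`, `event_id` for events). Referential invariants (every
#' cycle row has an existing parent whose dates bound it; every event
#' references an existing episode) are checked before writing.
#'
#' @param episodes Episode tibble in the EPISODE schema.
#' @param events Episode-event tibble in the EPISODE_EVENT schema.
#' @param directory Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_episode_tables <- function(episodes, events, directory) {
  check_episode_tables(episodes, events)
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  episodes <- episodes[order(episodes$person_id, episodes$episode_start_date,
                             episodes$episode_id), episode_columns]
  events <- events[order(events$episode_id, events$event_id),
                   episode_event_columns]
  ep_path <- file.path(directory, "EPISODE.csv")
  ev_path <- file.path(directory, "EPISODE_EVENT.csv")
  readr::write_csv(episodes, ep_path, progress = FALSE)
  readr::write_csv(events, ev_path, progress = FALSE)
  invisible(c(EPISODE = ep_path, EPISODE_EVENT = ev_path))
}

#' Read EPISODE / EPISODE_EVENT tables
#'
#' Inverse of [write_episode_tables()]: reading back what was written
#' reproduces both tibbles exactly.
#'
#' @param directory Directory holding `EPISODE.csv` and
#'   `EPISODE_EVENT.csv`.
#' @return A list with elements `episodes` and `events`.
#' @export
read_episode_tables <- function(directory) {
  episodes <- read_csv_checked(
    file.path(directory, "EPISODE.csv"), required = episode_columns,
    col_types = readr::cols(
      episode_id = readr::col_integer(),
      person_id = readr::col_integer(),
      episode_concept_id = readr::col_integer(),
      episode_start_date = readr::col_date(),
      episode_end_date = readr::col_date(),
      episode_parent_id = readr::col_integer(),
      episode_number = readr::col_integer(),
      episode_object_concept_id = readr::col_integer(),
      episode_source_value = readr::col_character()))
  events <- read_csv_checked(
    file.path(directory, "EPISODE_EVENT.csv"),
    required = episode_event_columns,
    col_types = readr::cols(
      episode_id = readr::col_integer(),
      event_id = readr::col_integer(),
      episode_event_field_concept_id = readr::col_integer()))
  check_episode_tables(episodes, events)
  list(episodes = episodes[, episode_columns],
       events = events[, episode_event_columns])
}
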