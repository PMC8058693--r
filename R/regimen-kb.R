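#' Construct a single regimen definition
#'
#' A regimen definition parameterizes one chemotherapy protocol for the
#' matching engine. Every component ingredient is assigned exactly one
#' role:
#'
#' * **index** drugs anchor day 1 of a treatment cycle: each dispense of
#'   an index drug (after merging near-duplicate dispense dates, see
#'   `min_cycle_gap_days`) opens a candidate cycle.
#' * **combination** drugs must all be dispensed at least once inside the
#'   cycle window for the cycle to match.
#' * **exclusion** drugs veto the match when dispensed inside the window;
#'   they distinguish a regimen from a superset regimen (for example
#'   bevacizumab distinguishes FOLFOX from FOLFOX plus bevacizumab).
#'
#' @param regimen_concept_id Integer concept identifier of the regimen
#'   (primary key within a library; in production use the HemOnc
#'   vocabulary identifier).
#' @param name Human-readable regimen name.
#' @param index_drugs Non-empty integer vector of ingredient concept IDs.
#' @param combination_drugs Integer vector of ingredient concept IDs
#'   (possibly empty for monotherapies).
#' @param exclusion_drugs Integer vector of ingredient concept IDs
#'   (possibly empty).
#' @param cycle_window_days Positive integer: a cycle spans
#'   `[index_date, index_date + cycle_window_days - 1]` (day inclusive);
#'   also the maximum start-date gap between consecutive cycles of one
#'   treatment episode.
#' @param line_window_days Positive integer, at least `cycle_window_days`:
#'   a start-date gap between consecutive treatment episodes beyond this
#'   window advances the treatment line even without a regimen change.
#' @param min_cycle_gap_days Positive integer: index-drug dispense dates
#'   closer than this to the previously retained index date are merged
#'   into one administration event (multi-day dispensing must not inflate
#'   cycle counts). Default 5 days.
#' @param meta Optional named list of document metadata: `origin`
#'   (protocol citation), `valid_start`, `valid_end` (ISO dates) and
#'   `invalid_reason`. If `invalid_reason` is given `valid_end` must be
#'   given too.
#' @param schedule Optional per-cycle administration template used by the
#'   synthetic cohort generator (and documentation): a list with
#'   `cycle_length_days`, `n_cycles_default`, and `components`, a list of
#'   `list(ingredient_concept_id, day_offsets, duration_days)` where
#'   `day_offsets` are 0-based offsets from cycle day 1.
#'
#' @return An object of class `regimen_definition`.
#' @seealso [regimen_library()], [builtin_regimen_library()]
#' @export
regimen_definition <- function(regimen_concept_id, name, index_drugs,
                               combination_drugs = integer(),
                               exclusion_drugs = integer(),
                               cycle_window_days, line_window_days,
                               min_cycle_gap_days = 5L,
                               meta = list(), schedule = NULL) {
  if (!is.null(schedule)) {
    schedule <- list(
      cycle_length_days = as.integer(schedule$cycle_length_days),
      n_cycles_default = as.integer(schedule$n_cycles_default),
      components = lapply(schedule$components, function(cmp) list(
        ingredient_concept_id = as.integer(cmp$ingredient_concept_id),
        day_offsets = as.integer(unname(unlist(cmp$day_offsets))),
        duration_days = as.integer(cmp$duration_days %||% 1L))))
  }
  if (length(meta) > 0L) meta <- meta[order(names(meta))]
  def <- structure(
    list(
      regimen_concept_id = as.integer(regimen_concept_id),
      name = as.character(name),
      index_drugs = sort(unique(as.integer(index_drugs))),
      combination_drugs = sort(unique(as.integer(combination_drugs))),
      exclusion_drugs = sort(unique(as.integer(exclusion_drugs))),
      cycle_window_days = as.integer(cycle_window_days),
      line_window_days = as.integer(line_window_days),
      min_cycle_gap_days = as.integer(min_cycle_gap_days),
      meta = meta,
      schedule = schedule
    ),
    class = "regimen_definition"
  )
  check_regimen_definition(def)
  def
}

check_regimen_definition <- function(def) {
  id <- def$regimen_concept_id
  fail <- function(field, msg) {
    stop(sprintf("regimen %s ('%s'): field '%s' %s",
                 id, def$name %||% "?", field, msg), call. = FALSE)
  }
  if (length(id) != 1L || is.na(id)) {
    fail("regimen_concept_id", "must be a single non-missing integer")
  }
  if (length(def$index_drugs) == 0L) {
    fail("index_drugs", "must be non-empty")
  }
  sets <- list(index_drugs = def$index_drugs,
               combination_drugs = def$combination_drugs,
               exclusion_drugs = def$exclusion_drugs)
  pairs <- utils::combn(names(sets), 2L, simplify = FALSE)
  for (p in pairs) {
    overlap <- intersect(sets[[p[1]]], sets[[p[2]]])
    if (length(overlap) > 0L) {
      fail(p[2], sprintf("overlaps %s on concept(s) %s", p[1],
                         paste(overlap, collapse = ", ")))
    }
  }
  for (w in c("cycle_window_days", "line_window_days", "min_cycle_gap_days")) {
    v <- def[[w]]
    if (length(v) != 1L || is.na(v) || v <= 0L) fail(w, "must be a positive integer")
  }
  if (def$line_window_days < def$cycle_window_days) {
    fail("line_window_days", "must be >= cycle_window_days")
  }
  if (!is.null(def$meta$invalid_reason) && is.null(def$meta$valid_end)) {
    fail("meta$invalid_reason", "requires meta$valid_end")
  }
  invisible(def)
}

#' All drugs an exposure to which can count as a cycle component
#' @noRd
component_drugs <- function(def) c(def$index_drugs, def$combination_drugs)

#' Construct a regimen library
#'
#' A library bundles regimen definitions with an explicit evaluation
#' order. The matching engine extracts regimens sequentially in that
#' order; records claimed by an earlier regimen are unavailable to later
#' ones, so the order matters when drug sets overlap.
#'
#' @param definitions List of [regimen_definition()] objects with unique
#'   `regimen_concept_id`s.
#' @param evaluation_order Optional integer vector, a permutation of the
#'   definition IDs. When `NULL`, definitions are ordered most-specific
#'   first: descending size of the index-plus-combination drug set, ties
#'   broken by ascending concept ID. This prevents a general regimen from
#'   consuming the records of its superset regimen.
#' @return An object of class `regimen_library`.
#' @export
regimen_library <- function(definitions, evaluation_order = NULL) {
  stopifnot(is.list(definitions))
  definitions <- unname(definitions)
  for (def in definitions) {
    if (!inherits(def, "regimen_definition")) {
      stop("all definitions must be regimen_definition objects", call. = FALSE)
    }
  }
  ids <- vapply(definitions, function(d) d$regimen_concept_id, integer(1))
  if (anyDuplicated(ids)) {
    stop("duplicate regimen_concept_id in library: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(evaluation_order)) {
    evaluation_order <- default_evaluation_order(definitions)
  } else {
    evaluation_order <- as.integer(evaluation_order)
    if (!setequal(evaluation_order, ids) ||
        length(evaluation_order) != length(ids)) {
      stop("evaluation_order must be a permutation of the definition IDs",
           call. = FALSE)
    }
  }
  # canonical storage order (ascending concept ID): the evaluation_order
  # field alone carries extraction precedence, and a sorted store makes
  # serialize/parse a strict round trip
  definitions <- definitions[order(ids)]
  names(definitions) <- as.character(sort(ids))
  structure(
    list(definitions = definitions, evaluation_order = evaluation_order),
    class = "regimen_library"
  )
}

#' Default most-specific-first evaluation order
#'
#' @param definitions List of [regimen_definition()] objects.
#' @return Integer vector of regimen concept IDs, descending size of
#'   index-plus-combination drug set, ties by ascending concept ID.
#' @export
default_evaluation_order <- function(definitions) {
  ids <- vapply(definitions, function(d) d$regimen_concept_id, integer(1))
  sizes <- vapply(definitions, function(d) length(component_drugs(d)), integer(1))
  ids[order(-sizes, ids)]
}

#' @export
print.regimen_definition <- function(x, ...) {
  cat(sprintf("<regimen_definition> %s (concept %d)\n", x$name,
              x$regimen_concept_id))
  cat("  index:      ", paste(x$index_drugs, collapse = ", "), "\n")
  cat("  combination:", paste(x$combination_drugs, collapse = ", "), "\n")
  cat("  exclusion:  ", paste(x$exclusion_drugs, collapse = ", "), "\n")
  cat(sprintf("  windows: cycle %dd, line %dd, min cycle gap %dd\n",
              x$cycle_window_days, x$line_window_days, x$min_cycle_gap_days))
  invisible(x)
}

#' @export
print.regimen_library <- function(x, ...) {
  cat(sprintf("<regimen_library> %d definition(s)\n", length(x$definitions)))
  for (id in x$evaluation_order) {
    d <- x$definitions[[as.character(id)]]
    cat(sprintf("  %d  %s\n", id, d$name))
  }
  invisible(x)
}

#' Parse a regimen knowledge base from JSON text
#'
#' The knowledge-base format is a UTF-8 JSON object
#' `{"regimens": [...], "evaluation_order": [...]}` with snake_case keys;
#' each regimen object carries the fields of [regimen_definition()]
#' (dates ISO-8601). `evaluation_order` may be omitted, in which case the
#' default most-specific-first order is derived.
#'
#' @param json_text Length-1 character: JSON source text.
#' @return A validated [regimen_library()].
#' @export
parse_regimen_kb <- function(json_text) {
  stopifnot(is.character(json_text), length(json_text) == 1L)
  raw <- tryCatch(
    jsonlite::fromJSON(json_text, simplifyVector = FALSE),
    error = function(e) {
      stop("malformed regimen KB JSON: ", conditionMessage(e), call. = FALSE)
    }
  )
  if (!is.list(raw) || is.null(raw$regimens)) {
    stop("regimen KB JSON must be an object with a 'regimens' array",
         call. = FALSE)
  }
  defs <- lapply(raw$regimens, parse_regimen_snippet)
  order <- if (!is.null(raw$evaluation_order)) {
    vapply(raw$evaluation_order, as.integer, integer(1))
  }
  regimen_library(defs, evaluation_order = order)
}

parse_regimen_snippet <- function(x) {
  ints <- function(v) if (is.null(v)) integer() else
    vapply(v, as.integer, integer(1))
  meta <- x$meta %||% list()
  schedule <- x$schedule
  regimen_definition(
    regimen_concept_id = as.integer(x$regimen_concept_id),
    name = as.character(x$name %||% paste0("regimen_", x$regimen_concept_id)),
    index_drugs = ints(x$index_drugs),
    combination_drugs = ints(x$combination_drugs),
    exclusion_drugs = ints(x$exclusion_drugs),
    cycle_window_days = as.integer(x$cycle_window_days),
    line_window_days = as.integer(x$line_window_days),
    min_cycle_gap_days = as.integer(x$min_cycle_gap_days %||% 5L),
    meta = meta,
    schedule = schedule
  )
}

#' Read a regimen knowledge base from a JSON file
#' @param path Path to a UTF-8 JSON knowledge-base file.
#' @return A validated [regimen_library()].
#' @export
read_regimen_kb <- function(path) {
  parse_regimen_kb(paste(readLines(path, encoding = "UTF-8"), collapse = "\n"))
}

#' Serialize a regimen library to canonical JSON text
#'
#' The output is key-sorted within each snippet and stable across runs,
#' so that `parse_regimen_kb(serialize_regimen_kb(lib))` reproduces `lib`
#' exactly and serialized libraries diff cleanly under version control.
#'
#' @param lib A [regimen_library()].
#' @return Length-1 character of pretty-printed JSON.
#' @export
serialize_regimen_kb <- function(lib) {
  stopifnot(inherits(lib, "regimen_library"))
  snippet <- function(def) {
    out <- list(
      combination_drugs = as.list(def$combination_drugs),
      cycle_window_days = def$cycle_window_days,
      exclusion_drugs = as.list(def$exclusion_drugs),
      index_drugs = as.list(def$index_drugs),
      line_window_days = def$line_window_days,
      meta = def$meta,
      min_cycle_gap_days = def$min_cycle_gap_days,
      name = def$name,
      regimen_concept_id = def$regimen_concept_id
    )
    if (!is.null(def$schedule)) {
      sch <- def$schedule
      out$schedule <- list(
        components = lapply(sch$components, function(cmp) list(
          day_offsets = as.list(cmp$day_offsets),
          duration_days = cmp$duration_days,
          ingredient_concept_id = cmp$ingredient_concept_id
        )),
        cycle_length_days = sch$cycle_length_days,
        n_cycles_default = sch$n_cycles_default
      )
    }
    out
  }
  body <- list(
    evaluation_order = as.list(lib$evaluation_order),
    regimens = lapply(lib$definitions[order(names(lib$definitions))], snippet)
  )
  jsonlite::toJSON(body, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                   null = "null")
}

#' Write a regimen library to a JSON file
#' @param lib A [regimen_library()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_regimen_kb <- function(lib, path) {
  writeLines(serialize_regimen_kb(lib), path, useBytes = TRUE)
  invisible(path)
}

#' Cross-regimen ambiguity diagnostics
#'
#' Flags regimen A when its index-plus-combination drug set is a strict
#' subset of regimen B's and B's extra drugs are not all listed among A's
#' exclusion drugs: exposures that realize B then also satisfy A, and
#' only the evaluation order decides which one wins. Adding B's extra
#' drugs to A's exclusion set removes the ambiguity.
#'
#' @param lib A [regimen_library()].
#' @return A tibble with columns `regimen_concept_id`, `ambiguous_with`,
#'   `missing_exclusions` (comma-separated concept IDs) and `message`;
#'   zero rows when the library is unambiguous.
#' @export
validate_regimen_library <- function(lib) {
  stopifnot(inherits(lib, "regimen_library"))
  defs <- lib$definitions
  out <- list()
  for (a in defs) {
    for (b in defs) {
      if (a$regimen_concept_id == b$regimen_concept_id) next
      set_a <- component_drugs(a)
      set_b <- component_drugs(b)
      if (all(set_a %in% set_b) && length(set_b) > length(set_a)) {
        extras <- setdiff(set_b, set_a)
        missing <- setdiff(extras, a$exclusion_drugs)
        if (length(missing) > 0L) {
          out[[length(out) + 1L]] <- tibble::tibble(
            regimen_concept_id = a$regimen_concept_id,
            ambiguous_with = b$regimen_concept_id,
            missing_exclusions = paste(missing, collapse = ","),
            message = sprintf(
              "'%s' matches whenever '%s' does; add exclusion drug(s) %s to '%s'",
              a$name, b$name, paste(missing, collapse = ", "), a$name)
          )
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(regimen_concept_id = integer(),
                          ambiguous_with = integer(),
                          missing_exclusions = character(),
                          message = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$regimen_concept_id,
                 .data$ambiguous_with)
}
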