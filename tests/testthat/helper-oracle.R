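# Independent reference matcher used to cross-check the extraction
# engine. Deliberately written as a plain day-by-day, row-by-row
# procedure over data frames: no shared helpers with the package
# internals beyond the regimen definition fields themselves.

oracle_extract_cycles <- function(exposures, library) {
  exposures <- as.data.frame(exposures)
  results <- list()
  for (pid in sort(unique(exposures$person_id))) {
    px <- exposures[exposures$person_id == pid, , drop = FALSE]
    px <- px[order(as.integer(px$start_date), px$record_id), , drop = FALSE]
    claimed <- c()
    for (rid in library$evaluation_order) {
      def <- library$definitions[[as.character(rid)]]
      # index dates: scan day by day over the person's span
      free <- px[!(px$record_id %in% claimed), , drop = FALSE]
      idx_days <- c()
      if (nrow(free) > 0L) {
        for (d in seq(min(as.integer(free$start_date)),
                      max(as.integer(free$start_date)))) {
          has_index <- FALSE
          for (r in seq_len(nrow(free))) {
            if (as.integer(free$start_date[r]) == d &&
                free$ingredient_concept_id[r] %in% def$index_drugs) {
              has_index <- TRUE
            }
          }
          if (has_index) {
            if (length(idx_days) == 0L ||
                d - idx_days[length(idx_days)] >= def$min_cycle_gap_days) {
              idx_days <- c(idx_days, d)
            }
          }
        }
      }
      for (k in seq_along(idx_days)) {
        d0 <- idx_days[k]
        d1 <- d0 + def$cycle_window_days - 1L
        if (k < length(idx_days)) d1 <- min(d1, idx_days[k + 1L] - 1L)
        # exclusion: ANY exposure (claimed or not) starting in window
        excluded <- FALSE
        for (r in seq_len(nrow(px))) {
          sd <- as.integer(px$start_date[r])
          if (sd >= d0 && sd <= d1 &&
              px$ingredient_concept_id[r] %in% def$exclusion_drugs) {
            excluded <- TRUE
          }
        }
        if (excluded) next
        # components: unclaimed index/combination exposures in window
        comp_rows <- c()
        for (r in seq_len(nrow(px))) {
          sd <- as.integer(px$start_date[r])
          if (sd >= d0 && sd <= d1 &&
              !(px$record_id[r] %in% claimed) &&
              px$ingredient_concept_id[r] %in%
                c(def$index_drugs, def$combination_drugs)) {
            comp_rows <- c(comp_rows, r)
          }
        }
        if (length(comp_rows) == 0L) next
        comp <- px[comp_rows, , drop = FALSE]
        if (!any(comp$ingredient_concept_id %in% def$index_drugs)) next
        all_comb <- TRUE
        for (g in def$combination_drugs) {
          if (!(g %in% comp$ingredient_concept_id)) all_comb <- FALSE
        }
        if (!all_comb) next
        idx_comp <- comp[comp$ingredient_concept_id %in% def$index_drugs, ,
                         drop = FALSE]
        results[[length(results) + 1L]] <- data.frame(
          person_id = pid,
          regimen_concept_id = def$regimen_concept_id,
          index_date = as.Date(d0, origin = "1970-01-01"),
          start_date = min(idx_comp$start_date),
          end_date = max(comp$end_date),
          components = paste(sort(comp$record_id), collapse = ","),
          stringsAsFactors = FALSE)
        claimed <- c(claimed, comp$record_id)
      }
    }
  }
  if (length(results) == 0L) {
    return(data.frame(person_id = integer(),
                      regimen_concept_id = integer(),
                      index_date = as.Date(character()),
                      start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      components = character()))
  }
  out <- do.call(rbind, results)
  out[order(out$person_id, out$start_date, out$regimen_concept_id), ,
      drop = FALSE]
}

# Flatten engine output to the oracle's comparable form.
cycles_to_comparable <- function(cycles) {
  data.frame(
    person_id = cycles$person_id,
    regimen_concept_id = cycles$regimen_concept_id,
    index_date = cycles$index_date,
    start_date = cycles$start_date,
    end_date = cycles$end_date,
    components = vapply(cycles$component_record_ids,
                        function(x) paste(sort(x), collapse = ","), ""),
    stringsAsFactors = FALSE)
}

# Random small instance generator for oracle equivalence tests.
random_case <- function() {
  pool <- 11:18
  n_reg <- sample(1:3, 1)
  defs <- list()
  for (j in seq_len(n_reg)) {
    drugs <- sample(pool, sample(2:4, 1))
    n_comb <- sample(0:(length(drugs) - 1L), 1)
    idx <- drugs[1]
    comb <- if (n_comb > 0) drugs[1 + seq_len(n_comb)] else integer()
    rest <- setdiff(pool, drugs)
    excl <- if (length(rest) > 0 && runif(1) < 0.5)
      sample(rest, 1) else integer()
    w <- sample(7:28, 1)
    defs[[j]] <- regimen_definition(
      900L + j, paste0("R", j), index_drugs = idx,
      combination_drugs = comb, exclusion_drugs = excl,
      cycle_window_days = w, line_window_days = w + sample(0:90, 1),
      min_cycle_gap_days = sample(3:7, 1))
  }
  lib <- regimen_library(defs)
  n_persons <- sample(1:5, 1)
  n_rows <- sample(5:60, 1)
  person <- sample(seq_len(n_persons), n_rows, replace = TRUE)
  ingredient <- sample(pool, n_rows, replace = TRUE)
  start <- day(sample(0:120, n_rows, replace = TRUE))
  dur <- sample(1:3, n_rows, replace = TRUE)
  exposures <- tibble::tibble(
    record_id = seq_len(n_rows), person_id = as.integer(person),
    drug_concept_id = as.integer(ingredient),
    ingredient_concept_id = as.integer(ingredient),
    start_date = start, end_date = start + dur - 1L)
  list(library = lib, exposures = exposures)
}
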