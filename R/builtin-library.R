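# Built-in fixture knowledge base.
#
# Concept IDs below are synthetic fixture identifiers (1000-series for
# ingredients, 2000-series for regimens), NOT real OMOP/HemOnc concept
# IDs. A production deployment swaps in a knowledge base keyed by the
# HemOnc regimen concepts and RxNorm ingredient concepts of its
# vocabulary; every function in this package treats concept IDs as
# opaque integers, so nothing else changes.

#' Fixture ingredient concept IDs
#'
#' Named integer vector of the synthetic ingredient concept IDs used by
#' the built-in regimen library and the cohort simulator.
#'
#' @return Named integer vector.
#' @export
chemo_ingredients <- function() {
  c(
    fluorouracil     = 1001L,
    leucovorin       = 1002L,
    oxaliplatin      = 1003L,
    irinotecan       = 1004L,
    capecitabine     = 1005L,
    bevacizumab      = 1006L,
    doxorubicin      = 1007L,
    cyclophosphamide = 1008L,
    epirubicin       = 1009L,
    methotrexate     = 1010L,
    docetaxel        = 1011L,
    paclitaxel       = 1012L,
    gefitinib        = 1013L,
    cisplatin        = 1014L,
    vinorelbine      = 1015L,
    pemetrexed       = 1016L,
    carboplatin      = 1017L,
    gemcitabine      = 1018L,
    filgrastim       = 1020L
  )
}

#' Fixture regimen concept IDs
#' @return Named integer vector mapping regimen short names to the
#'   synthetic regimen concept IDs of [builtin_regimen_library()].
#' @export
chemo_regimens <- function() {
  c(
    FOLFOX                  = 2001L,
    FOLFIRI                 = 2002L,
    FULV                    = 2003L,
    CapeOx                  = 2004L,
    `FOLFOX-Bev`            = 2005L,
    `capecitabine mono`     = 2006L,
    AC                      = 2007L,
    FEC                     = 2008L,
    FAC                     = 2009L,
    CMF                     = 2010L,
    Taxotere                = 2011L,
    `paclitaxel mono`       = 2012L,
    `doxorubicin mono`      = 2013L,
    `docetaxel mono`        = 2014L,
    `gefitinib mono`        = 2015L,
    `cisplatin+vinorelbine` = 2016L,
    `cisplatin+pemetrexed`  = 2017L,
    `carboplatin+gemcitabine` = 2018L,
    `carboplatin+paclitaxel`  = 2019L
  )
}

sched_component <- function(ingredient, day_offsets = 0L, duration_days = 1L) {
  list(ingredient_concept_id = as.integer(ingredient),
       day_offsets = as.integer(day_offsets),
       duration_days = as.integer(duration_days))
}

#' Built-in regimen library
#'
#' A curated fixture library of 19 common regimens for colorectal,
#' breast and lung cancer, each with documented cycle and line windows
#' and a per-cycle administration schedule template shared with the
#' cohort simulator (single source of truth for generator and matcher).
#'
#' Window convention: `cycle_window_days` is the protocol cycle length
#' plus a 7-day grace for treatment delays; `line_window_days` is 120
#' days for every regimen. Exclusion drugs are chosen so that the
#' library passes [validate_regimen_library()] with zero diagnostics
#' (each regimen whose drug set is contained in a superset regimen
#' excludes the superset's extra drugs).
#'
#' @return A [regimen_library()] in default most-specific-first order.
#' @export
builtin_regimen_library <- function() {
  ing <- chemo_ingredients()
  reg <- chemo_regimens()
  meta <- function(origin) list(origin = origin)

  defs <- list(
    regimen_definition(
      reg[["FOLFOX"]], "FOLFOX",
      index_drugs = ing[["oxaliplatin"]],
      combination_drugs = ing[c("fluorouracil", "leucovorin")],
      exclusion_drugs = ing[["bevacizumab"]],
      cycle_window_days = 21L, line_window_days = 120L,
      meta = meta("adjuvant FOLFOX, q14d x 12 cycles"),
      schedule = list(
        cycle_length_days = 14L, n_cycles_default = 12L,
        components = list(
          sched_component(ing[["oxaliplatin"]]),
          sched_component(ing[["leucovorin"]]),
          sched_component(ing[["fluorouracil"]], 0L, 2L)
        ))),
    regimen_definition(
      reg[["FOLFIRI"]], "FOLFIRI",
      index_drugs = ing[["irinotecan"]],
      combination_drugs = ing[c("fluorouracil", "leucovorin")],
      exclusion_drugs = ing[["bevacizumab"]],
      cycle_window_days = 21L, line_window_days = 120L,
      meta = meta("FOLFIRI, q14d"),
      schedule = list(
        cycle_length_days = 14L, n_cycles_default = 12L,
        components = list(
          sched_component(ing[["irinotecan"]]),
          sched_component(ing[["leucovorin"]]),
          sched_component(ing[["fluorouracil"]], 0L, 2L)
        ))),
    regimen_definition(
      reg[["FULV"]], "FULV",
      index_drugs = ing[["fluorouracil"]],
      combination_drugs = ing[["leucovorin"]],
      exclusion_drugs = ing[c("oxaliplatin", "irinotecan", "bevacizumab")],
      cycle_window_days = 35L, line_window_days = 120L,
      meta = meta("adjuvant fluorouracil + leucovorin, days 1-5 q28d x 6"),
      schedule = list(
        cycle_length_days = 28L, n_cycles_default = 6L,
        components = list(
          sched_component(ing[["fluorouracil"]], 0:4),
          sched_component(ing[["leucovorin"]], 0:4)
        ))),
    regimen_definition(
      reg[["CapeOx"]], "CapeOx",
      index_drugs = ing[["oxaliplatin"]],
      combination_drugs = ing[["capecitabine"]],
      exclusion_drugs = ing[c("fluorouracil", "bevacizumab")],
      cycle_window_days = 28L, line_window_days = 120L,
      meta = meta("adjuvant CapeOx, q21d x 8; capecitabine days 1-14"),
      schedule = list(
        cycle_length_days = 21L, n_cycles_default = 8L,
        components = list(
          sched_component(ing[["oxaliplatin"]]),
          sched_component(ing[["capecitabine"]], 0L, 14L)
        ))),
    regimen_definition(
      reg[["FOLFOX-Bev"]], "FOLFOX + bevacizumab",
      index_drugs = ing[["oxaliplatin"]],
      combination_drugs = ing[c("fluorouracil", "leucovorin", "bevacizumab")],
      cycle_window_days = 21L, line_window_days = 120L,
      meta = meta("FOLFOX + bevacizumab, q14d"),
      schedule = list(
        cycle_length_days = 14L, n_cycles_default = 12L,
        components = list(
          sched_component(ing[["oxaliplatin"]]),
          sched_component(ing[["leucovorin"]]),
          sched_component(ing[["bevacizumab"]]),
          sched_component(ing[["fluorouracil"]], 0L, 2L)
        ))),
    regimen_definition(
      reg[["capecitabine mono"]], "capecitabine monotherapy",
      index_drugs = ing[["capecitabine"]],
      exclusion_drugs = ing[c("oxaliplatin", "bevacizumab")],
      cycle_window_days = 28L, line_window_days = 120L,
      meta = meta("capecitabine days 1-14 q21d"),
      schedule = list(
        cycle_length_days = 21L, n_cycles_default = 8L,
        components = list(
          sched_component(ing[["capecitabine"]], 0L, 14L)
        ))),
    regimen_definition(
      reg[["AC"]], "AC",
      index_drugs = ing[["doxorubicin"]],
      combination_drugs = ing[["cyclophosphamide"]],
      exclusion_drugs = ing[c("fluorouracil", "docetaxel")],
      cycle_window_days = 28L, line_window_days = 120L,
      meta = meta("doxorubicin + cyclophosphamide, q21d x 4"),
      schedule = list(
        cycle_length_days = 21L, n_cycles_default = 4L,
        components = list(
          sched_component(ing[["doxorubicin"]]),
          sched_component(ing[["cyclophosphamide"]])
        ))),
    regimen_definition(
      reg[["FEC"]], "FEC",
      index_drugs = ing[["epirubicin"]],
      combination_drugs = ing[c("fluorouracil", "cyclophosphamide")],
      cycle_window_days = 28L, line_window_days = 120L,
      meta = meta("fluorouracil + epirubicin + cyclophosphamide, q21d x 6"),
      schedule = list(
        cycle_length_days = 21L, n_cycles_default = 6L,
        components = list(
          sched_component(ing[["epirubicin"]]),
          sched_component(ing[["fluorouracil"]]),
          sched_component(ing[["cyclophosphamide"]])
        ))),
    regimen_definition(
      reg[["FAC"]], "FAC",
      index_drugs = ing[["doxorubicin"]],
      combination_drugs = ing[c("fluorouracil", "cyclophosphamide")],
      cycle_window_days = 28L, line_window_days = 120L,
      meta = meta("fluorouracil + doxorubicin + cyclophosphamide, q21d x 6"),
      schedule = list(
        cycle_length_days = 21L, n_cycles_default = 6L,
        components = list(
          sched_component(ing[["doxorubicin"]]),
          sched_component(ing[["fluorouracil"]]),
          sched_component(ing[["cyclophosphamide"]])
        ))),
    regimen_definition(
      reg[["CMF"]], "CMF",
      index_drugs = ing[["methotrexate"]],
      combination_drugs = ing[c("cyclophosphamide", "fluorouracil")],
      exclusion_drugs = ing[["doxorubicin"]],
      cycle_window_days = 35L, line_window_days = 120L,
      # methotrexate days 1 and 8: min_cycle_gap 10 merges both dispenses
      # into one index event so the two administrations are one cycle
      min_cycle_gap_days = 10L,
      meta = meta("cyclophosphamide + methotrexate + fluorouracil, q28d x 6"),
      schedule = list(
        cycle_length_days = 28L, n_cycles_default = 6L,
        components = list(
          sched_component(ing[["methotrexate"]], c(0L, 7L)),
          sched_component(ing[["fluorouracil"]], c(0L, 7L)),
          sched_component(ing[["cyclophosphamide"]], 0L, 14L)
        ))),
    regimen_definition(
      reg[["Taxotere"]], "Taxotere (doxorubicin + docetaxel)",
      index_drugs = ing[["docetaxel"]],
      combination_drugs = ing[["doxorubicin"]],
      exclusion_drugs = ing[["cyclophosphamide"]],
      cycle_window_days = 28L, line_window_days = 120L,
      meta = meta("doxorubicin + docetaxel, q21d x 6"),
      schedule = list(
        cycle_length_days = 21L, n_cycles_default = 6L,
        components = list(
          sched_component(ing[["docetaxel"]]),
          sched_component(ing[["doxorubicin"]])
        ))),
    regimen_definition(
      reg[["paclitaxel mono"]], "paclitaxel monotherapy",
      index_drugs = ing[["paclitaxel"]],
      exclusion_drugs = ing[c("carboplatin", "doxorubicin")],
      cycle_window_days = 28L, line_window_days = 120L,
      meta = meta("paclitaxel q21d x 4"),
      schedule = list(
        cycle_length_days = 21L, n_cycles_default = 4L,
        components = list(sched_component(ing[["paclitaxel"]])))),
    regimen_definition(
      reg[["doxorubicin mono"]], "doxorubicin monotherapy",
      index_drugs = ing[["doxorubicin"]],
      exclusion_drugs = ing[c("cyclophosphamide", "docetaxel",
                              "fluorouracil")],
      cycle_window_days = 28L, line_window_days = 120L,
      meta = meta("doxorubicin q21d x 4"),
      schedule = list(
        cycle_length_days = 21L, n_cycles_default = 4L,
        components = list(sched_component(ing[["doxorubicin"]])))),
    regimen_definition(
      reg[["docetaxel mono"]], "docetaxel monotherapy",
      index_drugs = ing[["docetaxel"]],
      exclusion_drugs = ing[c("doxorubicin", "cisplatin")],
      cycle_window_days = 28L, line_window_days = 120L,
      meta = meta("docetaxel q21d x 4"),
      schedule = list(
        cycle_length_days = 21L, n_cycles_default = 4L,
        components = list(sched_component(ing[["docetaxel"]])))),
    regimen_definition(
      reg[["gefitinib mono"]], "gefitinib monotherapy",
      index_drugs = ing[["gefitinib"]],
      cycle_window_days = 35L, line_window_days = 120L,
      meta = meta("gefitinib continuous oral, 28-day dispensing"),
      schedule = list(
        cycle_length_days = 28L, n_cycles_default = 6L,
        components = list(sched_component(ing[["gefitinib"]], 0L, 28L)))),
    regimen_definition(
      reg[["cisplatin+vinorelbine"]], "cisplatin + vinorelbine",
      index_drugs = ing[["cisplatin"]],
      combination_drugs = ing[["vinorelbine"]],
      exclusion_drugs = ing[["pemetrexed"]],
      cycle_window_days = 28L, line_window_days = 120L,
      meta = meta("cisplatin day 1 + vinorelbine days 1,8, q21d x 4"),
      schedule = list(
        cycle_length_days = 21L, n_cycles_default = 4L,
        components = list(
          sched_component(ing[["cisplatin"]]),
          sched_component(ing[["vinorelbine"]], c(0L, 7L))
        ))),
    regimen_definition(
      reg[["cisplatin+pemetrexed"]], "cisplatin + pemetrexed",
      index_drugs = ing[["cisplatin"]],
      combination_drugs = ing[["pemetrexed"]],
      exclusion_drugs = ing[["vinorelbine"]],
      cycle_window_days = 28L, line_window_days = 120L,
      meta = meta("cisplatin + pemetrexed day 1, q21d x 4"),
      schedule = list(
        cycle_length_days = 21L, n_cycles_default = 4L,
        components = list(
          sched_component(ing[["cisplatin"]]),
          sched_component(ing[["pemetrexed"]])
        ))),
    regimen_definition(
      reg[["carboplatin+gemcitabine"]], "carboplatin + gemcitabine",
      index_drugs = ing[["carboplatin"]],
      combination_drugs = ing[["gemcitabine"]],
      exclusion_drugs = ing[["paclitaxel"]],
      cycle_window_days = 28L, line_window_days = 120L,
      meta = meta("carboplatin day 1 + gemcitabine days 1,8, q21d x 4"),
      schedule = list(
        cycle_length_days = 21L, n_cycles_default = 4L,
        components = list(
          sched_component(ing[["carboplatin"]]),
          sched_component(ing[["gemcitabine"]], c(0L, 7L))
        ))),
    regimen_definition(
      reg[["carboplatin+paclitaxel"]], "carboplatin + paclitaxel",
      index_drugs = ing[["carboplatin"]],
      combination_drugs = ing[["paclitaxel"]],
      exclusion_drugs = ing[["gemcitabine"]],
      cycle_window_days = 28L, line_window_days = 120L,
      meta = meta("carboplatin + paclitaxel day 1, q21d x 4"),
      schedule = list(
        cycle_length_days = 21L, n_cycles_default = 4L,
        components = list(
          sched_component(ing[["carboplatin"]]),
          sched_component(ing[["paclitaxel"]])
        )))
  )
  regimen_library(defs)
}
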