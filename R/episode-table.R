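#' Split an EPISODE table into treatment and cycle tibbles
#'
#' Converts rows of the oncology-extension EPISODE schema back into the
#' engine-level representation used by the analytics: one tibble of
#' treatment episodes (with `line_number` and the cycle count derived
#' from child rows) and one of cycles (with `cycle_number`).
#'
#' @param episodes Tibble in the EPISODE schema (see
#'   [read_episode_tables()]).
#' @param config A [cdm_config()] identifying the treatment and cycle
#'   episode concepts.
#' @return List of tibbles `treatments` (`episode_id`, `person_id`,
#'   `regimen_concept_id`, `episode_source_value`, `start_date`,
#'   `end_date`, `line_number`, `n_cycles`) and `cycles` (`episode_id`,
#'   `person_id`, `regimen_concept_id`, `parent_episode_id`,
#'   `cycle_number`, `start_date`, `end_date`).
#' @export
split_episode_table <- function(episodes, config = cdm_config()) {
  tr <- episodes[episodes$episode_concept_id ==
                   config$treatment_episode_concept_id, , drop = FALSE]
  cy <- episodes[episodes$episode_concept_id ==
                   config$cycle_episode_concept_id, , drop = FALSE]
  n_child <- table(factor(cy$episode_parent_id, levels = tr$episode_id))
  treatments <- tibble::tibble(
    episode_id = tr$episode_id,
    person_id = tr$person_id,
    regimen_concept_id = tr$episode_object_concept_id,
    episode_source_value = tr$episode_source_value,
    start_date = tr$episode_start_date,
    end_date = tr$episode_end_date,
    line_number = tr$episode_number,
    n_cycles = as.integer(n_child))
  cycles <- tibble::tibble(
    episode_id = cy$episode_id,
    person_id = cy$person_id,
    regimen_concept_id = cy$episode_object_concept_id,
    parent_episode_id = cy$episode_parent_id,
    cycle_number = cy$episode_number,
    start_date = cy$episode_start_date,
    end_date = cy$episode_end_date)
  list(treatments = treatments, cycles = cycles)
}
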