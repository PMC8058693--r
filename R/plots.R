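# Static figure helpers mirroring the standard displays for these
# analyses: a regimen-by-cycle-count heat map and a dot/violin onset
# plot. Trajectory results are emitted as node/edge tables suitable for
# any Sankey renderer; no interactive output is produced here.

require_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}

#' Heat map of cycle-iteration counts
#'
#' @param iteration_matrix Output of [cycle_iteration_matrix()]
#'   (suppressed cells are not drawn).
#' @param library Optional [regimen_library()] used to label regimens
#'   by name.
#' @return A ggplot object.
#' @export
plot_cycle_heatmap <- function(iteration_matrix, library = NULL) {
  require_ggplot2()
  df <- iteration_matrix[!iteration_matrix$suppressed, , drop = FALSE]
  df$regimen <- regimen_labels(df$regimen_concept_id, library)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_cycles, y = .data$regimen,
                                   fill = .data$n_patients)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient(low = "#deebf7", high = "#08306b",
                                 name = "patients") +
    ggplot2::labs(x = "treatment cycles completed", y = NULL) +
    ggplot2::theme_minimal()
}

#' Dot and violin plot of neutropenia onset timing
#'
#' @param onset Output of [onset_timing()].
#' @param library Optional [regimen_library()] for regimen names.
#' @return A ggplot object.
#' @export
plot_onset_timing <- function(onset, library = NULL) {
  require_ggplot2()
  onset$regimen <- regimen_labels(onset$regimen_concept_id, library)
  ggplot2::ggplot(onset, ggplot2::aes(x = .data$regimen,
                                      y = .data$gap_days)) +
    ggplot2::geom_violin(fill = "grey90", color = "grey60",
                         scale = "width") +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 0.8,
                         ggplot2::aes(color = .data$event_type)) +
    ggplot2::scale_y_continuous(breaks = c(2, 8, 15, 22, 29),
                                limits = c(0, 30)) +
    ggplot2::labs(x = NULL, y = "days from first chemotherapy",
                  color = "event") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1))
}

regimen_labels <- function(ids, library = NULL) {
  if (is.null(library)) return(as.character(ids))
  nm <- vapply(library$definitions, `[[`, character(1), "name")
  out <- nm[as.character(ids)]
  ifelse(is.na(out), as.character(ids), unname(out))
}
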