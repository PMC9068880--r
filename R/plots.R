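# ggplot2 views of a designed probe set: the probe map along the
# transcript and the design funnel.

#' Plot a probe set along its transcript
#'
#' Draws each selected binding footprint as a rectangle along the
#' transcript, colored by region, with the CDS shaded underneath. One
#' facet per transcript.
#'
#' @param object A `probe_set` from [design_probes()] or
#'   [select_pairs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot probe_set
#' @export
autoplot.probe_set <- function(object, ...) {
  pairs <- object$pairs
  if (nrow(pairs) == 0) abort("Probe set is empty; nothing to plot.")
  probes <- tibble(
    transcript_id = rep(pairs$transcript_id, each = 2),
    start = as.vector(rbind(pairs$p1_start, pairs$p2_start)),
    end = as.vector(rbind(pairs$p1_end, pairs$p2_end)),
    region = rep(as.character(pairs$region), each = 2)
  )
  p <- ggplot2::ggplot(probes) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = 0.1, ymax = 0.9, fill = .data$region),
      color = "grey20", linewidth = 0.1)
  tx <- object$transcripts
  if (!is.null(tx)) {
    cdss <- tx[!is.na(tx$cds_start), , drop = FALSE]
    if (nrow(cdss) > 0) {
      p <- p + ggplot2::geom_rect(
        data = tibble(transcript_id = cdss$id, start = cdss$cds_start,
                      end = cdss$cds_end),
        ggplot2::aes(xmin = .data$start, xmax = .data$end),
        ymin = -0.25, ymax = 0, fill = "grey55")
    }
    p <- p + ggplot2::geom_segment(
      data = tibble(transcript_id = tx$id, len = tx$length),
      ggplot2::aes(x = 0, xend = .data$len), y = -0.125, yend = -0.125,
      linewidth = 0.3, color = "grey30")
  }
  p +
    ggplot2::facet_wrap(~transcript_id, ncol = 1) +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "Region") +
    ggplot2::scale_y_continuous(breaks = NULL, limits = c(-0.35, 1)) +
    ggplot2::labs(x = "Transcript position (nt)", y = NULL,
                  title = "HCR probe-pair footprints") +
    ggplot2::theme_minimal()
}

#' Plot the design funnel
#'
#' Bar chart of the per-transcript funnel counts: candidate windows,
#' thermodynamic survivors, unique candidates, candidate pairs, selected
#' pairs.
#'
#' @param probe_set A `probe_set` with a design report (from
#'   [design_probes()]).
#' @return A ggplot object.
#' @export
plot_design_funnel <- function(probe_set) {
  rep <- probe_set$report
  if (is.null(rep)) abort("Probe set has no design report.")
  stages <- c("n_windows", "n_pass_thermo", "n_unique",
              "n_pairs_candidate", "n_pairs_selected")
  long <- tidyr::pivot_longer(rep[, c("transcript_id", stages)],
                              dplyr::all_of(stages),
                              names_to = "stage", values_to = "count")
  long$stage <- factor(long$stage, levels = stages,
                       labels = c("windows", "pass thermo", "unique",
                                  "candidate pairs", "selected pairs"))
  ggplot2::ggplot(long, ggplot2::aes(.data$stage, .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4,
                       size = 3) +
    ggplot2::facet_wrap(~transcript_id) +
    ggplot2::labs(x = NULL, y = "Count", title = "Design funnel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
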