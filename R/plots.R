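#' Plot the coverage profile of a gene
#'
#' Genomic (per-base Set-1) and junction-spanning (projected Set-2) coverage
#' across the gene's scaffold span, with the model's exons drawn underneath.
#'
#' @param object A [coverage_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coverage_profile
#' @export
autoplot.coverage_profile <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("genome_align", "border_align"),
                        names_to = "track", values_to = "depth")
  exons <- object$model
  ymin <- -max(1, max(d$depth)) * 0.06
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scaffold_pos, y = .data$depth,
                                  colour = .data$track)) +
    ggplot2::geom_step() +
    ggplot2::geom_rect(data = exons,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end),
                       ymin = ymin, ymax = ymin / 2,
                       inherit.aes = FALSE, fill = "grey30") +
    ggplot2::labs(x = paste0(object$scaffold_id, " position (bp)"),
                  y = "read alignments", colour = NULL,
                  title = paste0(object$gene_id, " (", object$strand, ")")) +
    ggplot2::theme_minimal()
}

#' Plot the outcome summary of a pipeline run
#'
#' @param object A `refine_run`.
#' @param ... Unused.
#' @return A ggplot bar chart of per-gene outcomes.
#' @method autoplot refine_run
#' @export
autoplot.refine_run <- function(object, ...) {
  d <- object$report |>
    count(.data$outcome)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$outcome, y = .data$n,
                                  fill = .data$outcome)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "gene models",
                  title = "Structural annotation outcome") +
    ggplot2::theme_minimal()
}
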