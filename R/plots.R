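# ggplot2 figures for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   geom_vline geom_hline labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a fragment-size distribution
#'
#' Bar plot of the 1-bp fragment-length histogram with the three
#' protection-mode peak-search windows marked.
#'
#' @param hist Tibble from [size_histogram()].
#' @param tf_window,core_window,chromatosome_window Windows as in
#'   [peak_ratio_metrics()]; drawn as dashed guides.
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(hist, tf_window = c(30, 80),
                                   core_window = c(140, 157),
                                   chromatosome_window = c(158, 180)) {
  guides <- c(tf_window, core_window, chromatosome_window)
  hist |>
    filter(.data$length <= 400) |>
    ggplot(aes(x = .data$length, y = .data$count)) +
    geom_col(width = 1) +
    geom_vline(xintercept = guides, linetype = "dashed", colour = "grey50") +
    labs(x = "fragment length (bp)", y = "fragments",
         title = "cfDNA fragment-size distribution") +
    theme_minimal()
}

#' @rdname plot_size_distribution
#' @param object,... `autoplot` method arguments (the histogram tibble).
#' @export
autoplot.cfdna_sizedist <- function(object, ...) plot_size_distribution(object, ...)

#' Plot an aggregate binding-site profile
#'
#' One depth-normalized occupancy curve per condition against the offset from
#' the binding-site center; the dip at offset 0 reflects TF binding.
#'
#' @param object A `cfdna_profile` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cfdna_profile <- function(object, ...) {
  ggplot(object$profile,
         aes(x = .data$offset, y = .data$occupancy,
             colour = .data$condition)) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_hline(yintercept = 1, linetype = "dotted", colour = "grey50") +
    labs(
      x = "offset from site center (bp)", y = "normalized cfDNA occupancy",
      title = sprintf("cfDNA occupancy around %s binding sites (n = %d)",
                      object$tf_name, object$n_sites),
      colour = "condition"
    ) +
    theme_minimal()
}

#' Plot differential-occupancy calls along the genome
#'
#' Relative occupancy change of every window stable in both conditions, with
#' the called gained/lost windows highlighted and the change threshold drawn.
#'
#' @param object A `cfdna_diff` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cfdna_diff <- function(object, ...) {
  st <- object$stats |>
    filter(.data$stable_both) |>
    mutate(direction = dplyr::case_when(
      .data$rel_change > object$change_min ~ "gained",
      .data$rel_change < -object$change_min ~ "lost",
      TRUE ~ "unchanged"
    ))
  ggplot(st, aes(x = .data$start, y = .data$rel_change,
                 colour = .data$direction)) +
    geom_point(size = 0.6) +
    geom_hline(yintercept = c(-1, 1) * object$change_min,
               linetype = "dashed", colour = "grey40") +
    facet_wrap(~chrom, nrow = 1, scales = "free_x") +
    labs(x = "window start (bp)", y = "relative occupancy change (post vs pre)",
         colour = NULL,
         title = sprintf("Differential cfDNA occupancy: %d gained, %d lost",
                         object$n_gained, object$n_lost)) +
    theme_minimal()
}
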