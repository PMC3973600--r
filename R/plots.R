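#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Genome-wide sliding-window profile plot
#'
#' Lines of per-window up- and down-regulation percentages with the GC content
#' overlaid (scaled to percent), faceted by replicon — the standard picture of
#' plasmid-biased up-regulation coinciding with reduced GC.
#'
#' @param profile Output of [sliding_window_profile()].
#' @return A ggplot object.
#' @export
plot_window_profile <- function(profile) {
  long <- profile |>
    dplyr::mutate(gc_pct = 100 * .data$gc_fraction) |>
    tidyr::pivot_longer(c("pct_up", "pct_down", "gc_pct"),
                        names_to = "track", values_to = "percent") |>
    dplyr::mutate(track = dplyr::recode(.data$track,
                                        pct_up = "% up-regulated",
                                        pct_down = "% down-regulated",
                                        gc_pct = "GC content (%)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window_index, y = .data$percent,
                                     colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$replicon), scales = "free_x") +
    ggplot2::labs(x = "window (genes in genomic order)", y = "percent",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of log2 fold changes across platforms
#'
#' @param object A `platform_comparison` from [compare_platforms()].
#' @param ... Unused.
#' @return A ggplot object annotated with Pearson's r.
#' @export
autoplot.platform_comparison <- function(object, ...) {
  pairs <- object$pairs
  finite <- is.finite(pairs$log2fc_a) & is.finite(pairs$log2fc_b)
  r <- object$summary$pearson_r
  ggplot2::ggplot(pairs[finite, ], ggplot2::aes(x = .data$log2fc_a, y = .data$log2fc_b)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
                      label = sprintf("r = %.2f", r)) +
    ggplot2::labs(x = paste0("log2 fold change (", object$labels[1], ")"),
                  y = paste0("log2 fold change (", object$labels[2], ")")) +
    ggplot2::theme_minimal()
}

#' Bar chart of up/down counts per COG category
#'
#' @param tally Output of [cog_tally()].
#' @return A ggplot object.
#' @export
plot_cog_tally <- function(tally) {
  long <- tally |>
    tidyr::pivot_longer(c("n_up", "n_down"), names_to = "direction",
                        values_to = "n") |>
    dplyr::mutate(direction = dplyr::recode(.data$direction,
                                            n_up = "up", n_down = "down"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cog_category, y = .data$n,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "COG category", y = "differentially expressed genes",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
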