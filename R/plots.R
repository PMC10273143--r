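#' Plot force-strain cycles of one filament
#'
#' Overlays the stretch and relax branches of every cycle, coloured by
#' cycle number (lighter = later), the standard way repeated
#' stretch-relax experiments are displayed.
#'
#' @param traces Trace table.
#' @param L0 Reference length (computed from the 5 pN crossing if omitted).
#' @return A ggplot object.
#' @export
plot_force_strain <- function(traces, L0 = NULL) {
  fs <- force_strain(traces, L0)
  fs$grp <- interaction(fs$cycle, fs$branch)
  ggplot2::ggplot(fs, ggplot2::aes(x = .data$eps, y = .data$F_pN,
                                   colour = .data$cycle,
                                   group = .data$grp)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::scale_colour_gradient(low = "#8B0000", high = "#FFB266") +
    ggplot2::labs(x = "strain", y = "force (pN)", colour = "cycle") +
    ggplot2::theme_classic()
}

#' Plot a cohort metric against cycle number with quartile band
#'
#' Thick line: median; shading: 25th-75th percentile band, the convention
#' used for cohort summaries of cyclically loaded filaments.
#'
#' @param metrics Row-bound [cycle_metrics()] across filaments.
#' @param var Metric column (e.g. `"eps_e"`, `"kappa_f"`, `"E_rel"`).
#' @return A ggplot object.
#' @export
plot_cycle_band <- function(metrics, var = "eps_e") {
  sm <- cohort_summary(metrics, var)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$cycle, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "cycle", y = var) +
    ggplot2::theme_classic()
}

#' Histogram with Freedman-Diaconis bin width
#'
#' @param values Numeric sample.
#' @param xlab Axis label.
#' @return A ggplot object.
#' @export
plot_fd_hist <- function(values, xlab = "value") {
  bw <- fd_binwidth(values)
  df <- data.frame(x = values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(binwidth = as.numeric(bw), fill = "grey40") +
    ggplot2::labs(x = xlab, y = "count") +
    ggplot2::theme_classic()
}
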