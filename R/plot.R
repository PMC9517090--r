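#' Plot a deviation field
#'
#' Histogram of the per-point deviations with the clinical acceptability
#' band and the RMS marked.
#'
#' @param object a `deviation_result` from [surface_deviation()].
#' @param threshold acceptability half-band in mm (drawn as dashed lines).
#' @param binwidth histogram bin width in mm.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.deviation_result <- function(object, threshold = 2,
                                      binwidth = 0.1, ...) {
  df <- tidy(object)
  rms <- object$summary$rms
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = rms, colour = "red") +
    ggplot2::labs(x = "deviation (mm)", y = "points",
                  title = sprintf("%s deviation, RMS = %.3f mm",
                                  object$reference_region, rms)) +
    ggplot2::theme_minimal()
  if (object$signed) {
    p <- p + ggplot2::geom_vline(xintercept = c(-threshold, threshold),
                                 linetype = "dashed")
  } else {
    p <- p + ggplot2::geom_vline(xintercept = threshold,
                                 linetype = "dashed")
  }
  p
}

#' Plot ICP convergence
#'
#' Per-iteration RMS of the optimized-alignment stage; the curve is
#' non-increasing after the first re-correspondence by construction of the
#' alternating minimisation.
#'
#' @param object a `registration_report` from [icp_refine()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.registration_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration, y = .data$rms)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "ICP iteration", y = "RMS over survivors (mm)") +
    ggplot2::theme_minimal()
}

#' Plot cohort 3D errors by group
#'
#' Dot plot of case-level RMS 3D errors per technique group with the
#' clinical threshold.
#'
#' @param cases the `cases` tibble from [run_cohort()].
#' @param threshold acceptability threshold (mm).
#' @return A ggplot object.
#' @export
plot_cohort_errors <- function(cases, threshold = 2) {
  ggplot2::ggplot(cases,
                  ggplot2::aes(x = .data$group, y = .data$rms_3d_error,
                               shape = .data$subgroup)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "red") +
    ggplot2::labs(x = NULL, y = "3D error, RMS (mm)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
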