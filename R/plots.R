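# ggplot2 displays for sweep results and cohort summaries.

#' Plot a tilt sweep
#'
#' Per-hip curves of LCEA, ACEA, and coverage against APP tilt angle,
#' faceted by measure.
#'
#' @param object a `tilt_sweep` tibble from [tilt_sweep()] or
#'   [measure_cohort()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.tilt_sweep <- function(object, ...) {
  long <- as_cohort_table(object)
  long$measure <- factor(long$measure, c("lcea", "acea", "coverage"),
                         c("LCEA (deg)", "ACEA (deg)", "Coverage"))
  ggplot2::ggplot(long, ggplot2::aes(.data$app_tilt_deg, .data$value,
                                     group = .data$hip_id,
                                     colour = .data$sex)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(x = "APP tilt (deg, + anterior)", y = NULL, colour = "sex") +
    ggplot2::theme_minimal()
}

#' Plot a per-angle sex comparison
#'
#' Mean curves by sex across the tilt grid, faceted by measure.
#'
#' @param object a `sex_summary` from [summarize_by_sex()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.sex_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("mean_male", "mean_female"),
    names_to = "sex", names_prefix = "mean_", values_to = "mean"
  )
  long$measure <- factor(long$measure, c("lcea", "acea", "coverage"),
                         c("LCEA (deg)", "ACEA (deg)", "Coverage"))
  ggplot2::ggplot(long, ggplot2::aes(.data$app_tilt_deg, .data$mean,
                                     colour = .data$sex)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(x = "APP tilt (deg, + anterior)", y = "group mean",
                  colour = "sex") +
    ggplot2::theme_minimal()
}
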