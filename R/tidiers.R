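# broom-style tidiers for the package's fitted objects.

#' Tidy a fitted head sphere
#'
#' @param x a [head_sphere()].
#' @param ... unused.
#' @return One-row tibble: `center_x`, `center_y`, `center_z`, `radius`.
#' @export
tidy.head_sphere <- function(x, ...) {
  tibble::tibble(center_x = x$center[1], center_y = x$center[2],
                 center_z = x$center[3], radius = x$radius)
}

#' @rdname tidy.head_sphere
#' @return `glance()`: one-row tibble with fit diagnostics `rms` and `n`.
#' @export
glance.head_sphere <- function(x, ...) {
  tibble::tibble(rms = x$rms, n = x$n)
}

#' Tidy a two-sample t-test result
#'
#' @param x a `hip_ttest` from [two_sample_ttest()] or [ttest_from_summary()].
#' @param ... unused.
#' @export
tidy.hip_ttest <- function(x, ...) {
  tibble::tibble(estimate = x$mean_a - x$mean_b, statistic = x$t,
                 df = x$df, p.value = x$p, method = x$method)
}

#' Tidy a labelled Pearson correlation
#'
#' @param x a `hip_cor` from [pearson_with_label()].
#' @param ... unused.
#' @export
tidy.hip_cor <- function(x, ...) {
  tibble::tibble(estimate = x$r, p.value = x$p, n = x$n,
                 strength_label = x$strength_label)
}

#' Tidy an ICC reliability result
#'
#' @param x a `hip_icc` from [icc_reliability()].
#' @param ... unused.
#' @export
tidy.hip_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, model_label = x$model_label,
                 msr = x$ms[["msr"]], msc = x$ms[["msc"]], mse = x$ms[["mse"]],
                 n = x$n, k = x$k)
}
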