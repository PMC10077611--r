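# Cohort-level statistics: sex comparisons per tilt angle, CEA-vs-coverage
# correlations, reliability, and the range/peak arithmetic used on the
# packaged published-cohort summary.

#' Independent two-sample t-test
#'
#' Student's pooled-variance test by default (`var_equal = TRUE`), Welch by
#' flag, two-sided. A degenerate case with zero variance in both groups and
#' equal means returns `t = 0, p = 1`; zero variance with unequal means is an
#' error.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param var_equal pooled (Student's) variance if `TRUE` (default), Welch
#'   otherwise.
#' @return An object of class `hip_ttest`: list with `t`, `df`, `p`,
#'   `mean_a`, `mean_b`, `method`.
#' @examples
#' two_sample_ttest(c(1, 2, 3), c(2, 3, 4))
#' @export
two_sample_ttest <- function(group_a, group_b, var_equal = TRUE) {
  group_a <- as.numeric(group_a)
  group_b <- as.numeric(group_b)
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 observations", class = "hipmorph_schema")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(new_hip_ttest(0, length(group_a) + length(group_b) - 2, 1,
                           mean(group_a), mean(group_b),
                           if (var_equal) "student" else "welch"))
    }
    abort("zero variance in both groups with unequal means: t undefined",
          class = "hipmorph_degenerate")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
  new_hip_ttest(unname(ht$statistic), unname(ht$parameter), ht$p.value,
                mean(group_a), mean(group_b),
                if (var_equal) "student" else "welch")
}

new_hip_ttest <- function(t, df, p, mean_a, mean_b, method) {
  structure(list(t = t, df = df, p = p, mean_a = mean_a, mean_b = mean_b,
                 method = method), class = "hip_ttest")
}

#' @export
print.hip_ttest <- function(x, ...) {
  cat(sprintf("<hip_ttest (%s)> t = %.4f, df = %.2f, p = %.4g\n",
              x$method, x$t, x$df, x$p))
  invisible(x)
}

#' Two-sample t-test from summary statistics
#'
#' Computes the identical statistic as [two_sample_ttest()] from per-group
#' `(n, mean, sd)` -- the form needed when only a published summary table is
#' available.
#'
#' @param n_a,mean_a,sd_a,n_b,mean_b,sd_b group summaries.
#' @inheritParams two_sample_ttest
#' @return A `hip_ttest`.
#' @export
ttest_from_summary <- function(n_a, mean_a, sd_a, n_b, mean_b, sd_b,
                               var_equal = TRUE) {
  if (n_a < 2 || n_b < 2) {
    abort("each group needs n >= 2", class = "hipmorph_schema")
  }
  if (sd_a == 0 && sd_b == 0) {
    if (mean_a == mean_b) {
      return(new_hip_ttest(0, n_a + n_b - 2, 1, mean_a, mean_b,
                           if (var_equal) "student" else "welch"))
    }
    abort("zero variance in both groups with unequal means: t undefined",
          class = "hipmorph_degenerate")
  }
  if (var_equal) {
    df <- n_a + n_b - 2
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  } else {
    va <- sd_a^2 / n_a
    vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  t <- (mean_a - mean_b) / se
  new_hip_ttest(t, df, 2 * stats::pt(-abs(t), df), mean_a, mean_b,
                if (var_equal) "student" else "welch")
}

cor_strength_label <- function(r) {
  a <- abs(r)
  if (a >= 0.8) "very strong"
  else if (a >= 0.6) "strong"
  else if (a >= 0.4) "moderate"
  else if (a >= 0.2) "weak"
  else "negligible"
}

#' Pearson correlation with a strength label
#'
#' Pearson r with a two-sided p-value and the conventional strength ladder
#' (|r| >= 0.8 very strong, >= 0.6 strong, >= 0.4 moderate, >= 0.2 weak,
#' else negligible; thresholds inclusive).
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return An object of class `hip_cor`: list with `r`, `p`, `n`,
#'   `strength_label`.
#' @export
pearson_with_label <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("need paired vectors of length >= 3", class = "hipmorph_schema")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("undefined correlation: zero variance", class = "hipmorph_degenerate")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 strength_label = cor_strength_label(unname(ct$estimate))),
            class = "hip_cor")
}

#' @export
print.hip_cor <- function(x, ...) {
  cat(sprintf("<hip_cor> r = %.3f (%s), p = %.4g, n = %d\n",
              x$r, x$strength_label, x$p, x$n))
  invisible(x)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC from the
#' standard mean-squares decomposition:
#' `(MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)`.
#'
#' @param ratings a complete numeric matrix, subjects in rows (>= 5), raters
#'   or sessions in columns (>= 2).
#' @return An object of class `hip_icc`: list with `icc`, `model_label`,
#'   mean squares `ms`.
#' @export
icc_reliability <- function(ratings) {
  m <- as.matrix(ratings)
  if (any(!is.finite(m))) {
    abort("ratings matrix must be complete (no missing values)", class = "hipmorph_schema")
  }
  n <- nrow(m)
  k <- ncol(m)
  if (n < 5 || k < 2) {
    abort("need >= 5 subjects and >= 2 raters", class = "hipmorph_schema")
  }
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(icc = icc,
                 model_label = "two-way random, absolute agreement, single measures (ICC(2,1))",
                 ms = c(msr = msr, msc = msc, mse = mse), n = n, k = k),
            class = "hip_icc")
}

#' @export
print.hip_icc <- function(x, ...) {
  cat(sprintf("<hip_icc> ICC = %.4f [%s; n = %d, k = %d]\n",
              x$icc, x$model_label, x$n, x$k))
  invisible(x)
}

check_cohort_table <- function(table) {
  need <- c("sex", "app_tilt_deg", "measure", "value")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    abort(paste0("cohort table is missing columns: ",
                 paste(missing, collapse = ", ")), class = "hipmorph_schema")
  }
  table
}

#' Per-angle sex comparison (published-table shape)
#'
#' For every (tilt angle, measure) stratum: n, mean, SD per sex and the
#' two-sided independent two-sample t-test p-value. Both sexes must be
#' present at every angle.
#'
#' @param table a long cohort table (see [as_cohort_table()]).
#' @param var_equal pooled t (default) or Welch.
#' @return A tibble of class `sex_summary`, one row per (angle, measure):
#'   `app_tilt_deg`, `measure`, `n_male`, `mean_male`, `sd_male`, `n_female`,
#'   `mean_female`, `sd_female`, `mean_overall`, `sd_overall`, `t`, `p`.
#' @export
summarize_by_sex <- function(table, var_equal = TRUE) {
  table <- check_cohort_table(table)
  strata <- dplyr::distinct(table, .data$app_tilt_deg, .data$measure)
  missing <- dplyr::anti_join(
    tidyr::crossing(strata, sex = c("male", "female")),
    dplyr::distinct(table, .data$app_tilt_deg, .data$measure, .data$sex),
    by = c("app_tilt_deg", "measure", "sex")
  )
  if (nrow(missing)) {
    abort(paste0(
      "missing sex stratum: ",
      paste(sprintf("%s/%s at %+g deg", missing$sex, missing$measure,
                    missing$app_tilt_deg), collapse = "; ")
    ), class = "hipmorph_validation")
  }
  out <- table |>
    dplyr::filter(.data$sex %in% c("male", "female")) |>
    dplyr::group_by(.data$app_tilt_deg, .data$measure) |>
    dplyr::summarise(
      n_male = sum(.data$sex == "male"),
      mean_male = mean(.data$value[.data$sex == "male"]),
      sd_male = sd(.data$value[.data$sex == "male"]),
      n_female = sum(.data$sex == "female"),
      mean_female = mean(.data$value[.data$sex == "female"]),
      sd_female = sd(.data$value[.data$sex == "female"]),
      mean_overall = mean(.data$value),
      sd_overall = sd(.data$value),
      t = two_sample_ttest(.data$value[.data$sex == "male"],
                           .data$value[.data$sex == "female"],
                           var_equal = var_equal)$t,
      p = two_sample_ttest(.data$value[.data$sex == "male"],
                           .data$value[.data$sex == "female"],
                           var_equal = var_equal)$p,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$app_tilt_deg, .data$measure)
  class(out) <- c("sex_summary", class(out))
  out
}

# Per-angle group means from either a raw long table (column `value`) or a
# pre-summarized table (columns `group`, `mean`).
per_angle_means <- function(table, group) {
  if ("value" %in% names(table)) {
    table <- check_cohort_table(table)
    if (group != "overall") table <- dplyr::filter(table, .data$sex == group)
    if (!nrow(table)) {
      abort(paste0("no rows for group ", group), class = "hipmorph_validation")
    }
    dplyr::summarise(dplyr::group_by(table, .data$measure, .data$app_tilt_deg),
                     mean = mean(.data$value), .groups = "drop")
  } else if (all(c("group", "mean") %in% names(table))) {
    grp <- if (group %in% c("male", "men")) "men"
           else if (group %in% c("female", "women")) "women"
           else "overall"
    out <- dplyr::select(dplyr::filter(table, .data$group == grp),
                         "measure", "app_tilt_deg", "mean")
    if (!nrow(out)) {
      abort(paste0("no rows for group ", grp), class = "hipmorph_validation")
    }
    out
  } else {
    abort("table must have a `value` column (raw) or `group`/`mean` columns (summary)",
          class = "hipmorph_schema")
  }
}

#' Range and peak of per-angle group means
#'
#' For each measure: the difference between the maximum and minimum of the
#' per-angle group means over a tilt window, and the angle attaining the
#' maximum (ties broken toward the smaller angle). Accepts either a raw long
#' cohort table or a pre-summarized means table such as [table1_summary()].
#'
#' @param table long cohort table (`value` column) or summary table
#'   (`group`, `mean` columns).
#' @param angle_lo,angle_hi tilt window in degrees (inclusive).
#' @param group `"overall"`, `"male"`/`"men"`, or `"female"`/`"women"`.
#' @return A tibble, one row per measure: `measure`, `range`, `argmax_deg`,
#'   `max`, `min`, `n_angles`.
#' @examples
#' range_stats(table1_summary(), -10, 5, "overall")
#' @export
range_stats <- function(table, angle_lo, angle_hi, group = "overall") {
  means <- per_angle_means(table, group)
  means <- dplyr::filter(means, .data$app_tilt_deg >= angle_lo,
                         .data$app_tilt_deg <= angle_hi)
  if (!nrow(means)) {
    abort("empty angle window", class = "hipmorph_validation")
  }
  means |>
    dplyr::group_by(.data$measure) |>
    dplyr::arrange(.data$app_tilt_deg, .by_group = TRUE) |>
    dplyr::summarise(
      range = max(.data$mean) - min(.data$mean),
      argmax_deg = .data$app_tilt_deg[which.max(.data$mean)],
      max = max(.data$mean), min = min(.data$mean),
      n_angles = dplyr::n(), .groups = "drop"
    )
}

#' CEA-vs-coverage correlations per sex and angle
#'
#' Pearson correlation of each center-edge angle with coverage within sex at
#' each tilt angle, with the conventional strength labels.
#'
#' @param table a long cohort table with `acea`/`lcea`/`coverage` measures.
#' @return A tibble, one row per (sex, angle, CEA measure): `sex`,
#'   `app_tilt_deg`, `cea_measure`, `r`, `p`, `n`, `strength_label`.
#' @export
correlation_by_angle <- function(table) {
  table <- check_cohort_table(table)
  wide <- tidyr::pivot_wider(
    dplyr::select(table, dplyr::any_of(c("hip_id", "subject_id", "side")),
                  "sex", "app_tilt_deg", "measure", "value"),
    names_from = "measure", values_from = "value"
  )
  wide |>
    tidyr::pivot_longer(cols = dplyr::any_of(c("acea", "lcea")),
                        names_to = "cea_measure", values_to = "cea") |>
    dplyr::group_by(.data$sex, .data$app_tilt_deg, .data$cea_measure) |>
    dplyr::group_modify(function(d, key) {
      ct <- pearson_with_label(d$cea, d$coverage)
      tibble::tibble(r = ct$r, p = ct$p, n = ct$n,
                     strength_label = ct$strength_label)
    }) |>
    dplyr::ungroup()
}

#' Packaged published-cohort summary table
#'
#' Per-angle means and SDs of ACEA, LCEA, and coverage for a published CT
#' cohort of 142 normal adult hips (76 men, 66 women), overall and by sex,
#' over the -30..+30 degree APP tilt grid. Shipped as a plain-CSV fixture
#' and used for range/peak arithmetic that needs only the printed summary.
#'
#' @return A tibble with columns `app_tilt_deg`, `measure`, `group`
#'   (`overall`/`men`/`women`), `n`, `mean`, `sd`.
#' @export
table1_summary <- function() {
  path <- system.file("extdata", "table1_cohort_summary.csv", package = "hipmorph")
  readr::read_csv(path, show_col_types = FALSE, comment = "#")
}
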