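test_that("pooled t-test reproduces the hand-computed textbook value", {
  res <- two_sample_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(res$t, -1.2247, tolerance = 1e-4)
  expect_equal(res$df, 4)
  same <- two_sample_ttest(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_ttest(1, c(1, 2)), class = "hipmorph_schema")
  expect_error(two_sample_ttest(c(1, 1, 1), c(2, 2, 2)),
               class = "hipmorph_degenerate")
})

test_that("summary-statistic t equals the raw-data t on random cohorts", {
  withr::local_seed(21)
  for (i in 1:20) {
    a <- rnorm(sample(5:40, 1), rnorm(1), runif(1, 0.5, 3))
    b <- rnorm(sample(5:40, 1), rnorm(1), runif(1, 0.5, 3))
    for (ve in c(TRUE, FALSE)) {
      raw <- two_sample_ttest(a, b, var_equal = ve)
      summ <- ttest_from_summary(length(a), mean(a), sd(a),
                                 length(b), mean(b), sd(b), var_equal = ve)
      expect_equal(raw$t, summ$t, tolerance = 1e-12)
      expect_equal(raw$df, summ$df, tolerance = 1e-12)
      expect_equal(raw$p, summ$p, tolerance = 1e-12)
    }
  }
})

test_that("correlation strength labels follow the conventional ladder", {
  perfect <- pearson_with_label(1:10, 2 * (1:10) + 1)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$strength_label, "very strong")

  for (case in list(c(0.721, NA), c(0.568, NA), c(0.60, NA), c(0.30, NA),
                    c(0.10, NA))) {
    d <- make_cor_data(case[1])
    res <- pearson_with_label(d$x, d$y)
    expect_equal(res$r, case[1], tolerance = 1e-10)
  }
  expect_equal(pearson_with_label(make_cor_data(0.721)$x, make_cor_data(0.721)$y)$strength_label,
               "strong")
  expect_equal(pearson_with_label(make_cor_data(0.568)$x, make_cor_data(0.568)$y)$strength_label,
               "moderate")
  # boundary is inclusive
  expect_equal(pearson_with_label(make_cor_data(0.60)$x, make_cor_data(0.60)$y)$strength_label,
               "strong")

  # orthogonal-by-construction pairs give r = 0
  x <- c(-2, -1, 1, 2)
  y <- c(4, 1, 1, 4)
  expect_lt(abs(pearson_with_label(x, y)$r), 1e-12)
  expect_error(pearson_with_label(rep(1, 5), 1:5), class = "hipmorph_degenerate")
})

test_that("ICC(2,1) matches the aov mean-squares oracle", {
  ident <- matrix(rep(c(3, 8, 1, 5, 9, 4), 2), ncol = 2)
  expect_equal(icc_reliability(ident)$icc, 1)

  withr::local_seed(13)
  subj <- rnorm(6, 0, 5)
  m <- cbind(subj, subj + 1.0)
  res <- icc_reliability(m)
  expect_equal(res$icc, oracle_icc_aov(m), tolerance = 1e-10)

  noise <- matrix(rnorm(60), ncol = 2)
  res_noise <- icc_reliability(noise)
  expect_equal(res_noise$icc, oracle_icc_aov(noise), tolerance = 1e-10)
  expect_lt(abs(res_noise$icc), 0.35)

  m_na <- m
  m_na[2, 1] <- NA
  expect_error(icc_reliability(m_na), class = "hipmorph_schema")
  expect_error(icc_reliability(m[1:3, ]), class = "hipmorph_schema")
})

make_long_table <- function(n_per_sex = 10, seed = 3) {
  withr::with_seed(seed, {
    tidyr::crossing(
      hip_id = sprintf("h%02d", 1:(2 * n_per_sex)),
      app_tilt_deg = c(-10, 0, 10),
      measure = c("acea", "lcea", "coverage")
    ) |>
      dplyr::mutate(
        sex = rep(rep(c("male", "female"), each = n_per_sex), each = 9),
        value = rnorm(dplyr::n(), 30, 5) +
          2 * (sex == "male")
      )
  })
}

test_that("sex summaries are relabeling-symmetric and detect missing strata", {
  tab <- make_long_table()
  s1 <- summarize_by_sex(tab)
  swapped <- dplyr::mutate(tab, sex = ifelse(sex == "male", "female", "male"))
  s2 <- summarize_by_sex(swapped)
  expect_equal(s1$mean_male, s2$mean_female, tolerance = 1e-12)
  expect_equal(s1$sd_female, s2$sd_male, tolerance = 1e-12)
  expect_equal(s1$t, -s2$t, tolerance = 1e-12)
  expect_equal(s1$p, s2$p, tolerance = 1e-12)
  err <- expect_error(summarize_by_sex(dplyr::filter(tab, sex == "male")),
                      class = "hipmorph_validation")
  expect_match(conditionMessage(err), "female")
})

test_that("range statistics reproduce the published-summary arithmetic exactly", {
  tab <- table1_summary()
  expect_equal(nrow(tab), 117)
  phys <- range_stats(tab, -10, 5, "overall")
  expect_equal(phys$range[phys$measure == "acea"], 11.77, tolerance = 1e-9)
  expect_equal(phys$range[phys$measure == "lcea"], 1.84, tolerance = 1e-9)
  expect_equal(phys$range[phys$measure == "coverage"], 0.05, tolerance = 1e-9)
  men <- range_stats(tab, -10, 5, "men")
  women <- range_stats(tab, -10, 5, "women")
  expect_equal(men$range[men$measure == "lcea"], 1.52, tolerance = 1e-9)
  expect_equal(women$range[women$measure == "lcea"], 2.22, tolerance = 1e-9)
  full <- range_stats(tab, -30, 30, "overall")
  expect_equal(full$argmax_deg[full$measure == "lcea"], 10)
  expect_equal(full$argmax_deg[full$measure == "coverage"], 10)
  expect_error(range_stats(tab, 40, 50), class = "hipmorph_validation")
})

test_that("range statistics are invariant to row order and table duplication", {
  tab <- make_long_table()
  base <- range_stats(tab, -10, 10, "overall")
  shuffled <- withr::with_seed(4, dplyr::slice_sample(tab, prop = 1))
  expect_equal(range_stats(shuffled, -10, 10, "overall"), base)
  doubled <- dplyr::bind_rows(tab, tab)
  expect_equal(range_stats(doubled, -10, 10, "overall"), base)
  const <- dplyr::mutate(tab, value = 7)
  expect_true(all(range_stats(const, -10, 10)$range == 0))
  # ties break toward the smaller angle
  expect_equal(range_stats(const, -10, 10)$argmax_deg, rep(-10, 3))
})

test_that("per-angle correlations label strata and reject degenerate ones", {
  tab <- make_long_table(n_per_sex = 15, seed = 6)
  # make coverage co-vary with the CEAs within each stratum
  wide <- tidyr::pivot_wider(tab, names_from = measure, values_from = value)
  wide$coverage <- (wide$lcea + wide$acea) / 100
  long <- tidyr::pivot_longer(wide, cols = c("acea", "lcea", "coverage"),
                              names_to = "measure", values_to = "value")
  res <- correlation_by_angle(long)
  expect_equal(nrow(res), 2 * 3 * 2)
  expect_true(all(res$r > 0))
  expect_true(all(res$strength_label %in%
                    c("negligible", "weak", "moderate", "strong", "very strong")))
  dup <- dplyr::mutate(long, value = ifelse(measure == "coverage", 0.5, value))
  expect_error(correlation_by_angle(dup), class = "hipmorph_degenerate")
})

test_that("tidiers return one-row tibbles with the fitted quantities", {
  fit <- fit_head_sphere(sweep(24 * fib_sphere_points(100), 2, c(1, 2, 3), "+"))
  td <- tidy(fit)
  expect_equal(td$radius, 24, tolerance = 1e-6)
  expect_equal(glance(fit)$n, 100)
  tt <- tidy(two_sample_ttest(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(tt$statistic, -1.2247, tolerance = 1e-4)
  ic <- tidy(icc_reliability(matrix(rnorm(12), ncol = 2)))
  expect_true(all(c("icc", "msr", "mse") %in% names(ic)))
})
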