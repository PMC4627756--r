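test_that("every published range row is reproduced from its estimate triple", {
  tab <- published_ranges()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    out <- triangulate(c(re_mean = row$re, lo = row$lowest, hi = row$highest))
    expect_equal(out$lowest, row$lowest, info = row$distribution)
    expect_equal(out$highest, row$highest, info = row$distribution)
    expect_equal(out$bre_abs, row$bre_abs, tolerance = 1e-9, info = row$distribution)
    expect_equal(out$bre_pct, row$bre_pct, info = row$distribution)
    expect_equal(out$bre_class, row$bre_class, info = row$distribution)
    expect_equal(out$mre_abs, row$mre_abs, tolerance = 1e-9, info = row$distribution)
    expect_equal(out$mre_pct, row$mre_pct, info = row$distribution)
    expect_equal(out$mre_class, row$mre_class, info = row$distribution)
    expect_equal(out$conclusion, row$conclusion, info = row$distribution)
  }
})

test_that("the baseline range never exceeds the maximum range", {
  set.seed(55)
  for (i in 1:200) {
    est <- c(re_mean = runif(1, 0.05, 0.4), a = runif(1, 0.01, 0.4),
             b = runif(1, 0.01, 0.4), c = runif(1, 0.01, 0.4))
    out <- triangulate(est)
    expect_lte(out$bre_abs, out$mre_abs + 1e-12)
    expect_lte(out$bre_pct_raw, out$mre_pct_raw + 1e-9)
    expect_gte(out$re_mean, out$lowest)
    expect_lte(out$re_mean, out$highest)
  }
})

test_that("classification bands and their boundaries are respected", {
  expect_equal(as.character(range_classify(25)), "moderate")
  expect_equal(as.character(range_classify(40)), "large")
  expect_equal(as.character(range_classify(16)), "negligible")
  expect_equal(as.character(range_classify(c(0, 19.9, 20, 39.9, 63))),
               c("negligible", "negligible", "moderate", "moderate", "large"))
  expect_error(range_classify(-1), "non-negative")
  # monotone in severity
  pcts <- sort(runif(50, 0, 80))
  cls <- range_classify(pcts)
  expect_true(all(diff(as.integer(cls)) >= 0))
})

test_that("conclusion strings order classes mild to severe", {
  expect_equal(range_conclusion("moderate", "moderate"), "Moderate difference")
  expect_equal(range_conclusion("negligible", "moderate"), "Negligible to moderate difference")
  expect_equal(range_conclusion("moderate", "large"), "Moderate to large difference")
  expect_equal(range_conclusion("large", "negligible"), "Negligible to large difference")
  expect_error(range_conclusion("tiny", "large"), "negligible")
})

test_that("degenerate estimate sets are handled explicitly", {
  out <- triangulate(c(re_mean = 0.2, a = 0.2, b = 0.2))
  expect_equal(out$bre_abs, 0)
  expect_equal(out$mre_abs, 0)
  expect_equal(out$conclusion, "Negligible difference")
  expect_error(triangulate(c(re_mean = 0.2)), "at least 2")
  expect_error(triangulate(c(re_mean = 0, a = 0.1)), "undefined")
  expect_error(triangulate(c(a = 0.1, b = 0.2)), "re_mean")
})

test_that("the estimate set maps battery fields and honours exclusions", {
  row <- tibble::tibble(
    distribution = "x", re_mean = .16, fe_mean = .15, osr_min = .16,
    osr_median = .16, osr_max = .16, tf_mean = .13, sm_moderate = .14,
    sm_severe = .12, pet_peese = .13, p_uniform = .19
  )
  est <- collect_estimates(row)
  expect_length(est, 9)
  expect_false("p_uniform" %in% names(est))
  est_pu <- collect_estimates(row, include_p_uniform = TRUE)
  expect_length(est_pu, 10)
  expect_equal(unname(est_pu["p_uniform"]), .19)
  # a not-applicable severe model drops out of the range scan
  row_na <- row
  row_na$sm_severe <- NA_real_
  out <- triangulate(collect_estimates(row_na))
  expect_equal(out$lowest, .13)
  expect_error(collect_estimates(dplyr::select(row, -re_mean)), "re_mean")
  # full-row triangulation reproduces the published full-distribution row
  out_full <- triangulate(est)
  expect_equal(out_full$lowest, .12)
  expect_equal(out_full$bre_pct, 25)
  expect_equal(out_full$conclusion, "Moderate difference")
})

test_that("utility arithmetic matches the worked selection example", {
  expect_equal(performance_sd_dollars(44888), 17955.20)
  expect_equal(utility_difference(.19, .19, 100, 20, 44888), 0)
  u85 <- utility_difference(.19, .14, 100, 20, 44888, selectee_z = 1.0364)
  u10 <- utility_difference(.19, .14, 100, 20, 44888, selectee_z = 1.0)
  expect_equal(u85, 100 * 20 * 17955.20 * 0.05 * 1.0364)
  expect_equal(u10, 1795520, tolerance = 1e-9)
  expect_gt(u85, 1.75e6); expect_lt(u85, 1.90e6)
  expect_error(utility_difference(1.1, .2, 100, 20, 44888), "in \\(-1, 1\\)")
  expect_error(utility_difference(.2, .1, -5, 20, 44888), "positive")
})
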