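test_that("PET and PEESE intercepts solve the WLS normal equations", {
  r <- c(0.10, 0.14, 0.20)
  se <- c(0.05, 0.10, 0.15)
  n <- round((1 - r^2)^2 / se^2 + 1)        # invert the raw-r variance
  d <- toy_studies(r, n)
  d$se <- se                                # exact SEs via the override
  pp <- pet_peese(d)
  wls <- function(X) {
    W <- diag(1 / se^2)
    solve(t(X) %*% W %*% X, t(X) %*% W %*% r)
  }
  beta_pet <- wls(cbind(1, se))
  beta_peese <- wls(cbind(1, se^2))
  expect_equal(pp$pet_estimate, beta_pet[1], tolerance = 1e-10)
  expect_equal(pp$slope_pet, beta_pet[2], tolerance = 1e-10)
  expect_equal(pp$peese_estimate, beta_peese[1], tolerance = 1e-10)
  expect_equal(pp$slope_peese, beta_peese[2], tolerance = 1e-10)
})

test_that("flat data give a zero PET slope and the common intercept", {
  d <- toy_studies(rep(0.2, 5), c(40, 80, 120, 200, 350))
  pp <- pet_peese(d)
  expect_equal(pp$pet_estimate, 0.2, tolerance = 1e-10)
  expect_equal(pp$slope_pet, 0, tolerance = 1e-8)
})

test_that("the PET/PEESE selection rule follows the one-tailed intercept test", {
  # strong positive effect at every precision: PET intercept significant,
  # so PEESE is selected
  set.seed(60)
  n <- sample(50:400, 30, replace = TRUE)
  v <- (1 - 0.3^2)^2 / (n - 1)
  d <- toy_studies(rnorm(30, 0.3, sqrt(v)), n)
  pp <- pet_peese(d)
  expect_lt(pp$pet_p_one_tailed, 0.05)
  expect_identical(pp$selected, pp$peese_estimate)
  # a flat null effect: PET intercept indistinguishable from zero,
  # PET intercept selected
  d0 <- toy_studies(c(0.02, -0.01, 0.03, -0.02, 0.01, -0.03),
                    c(40, 60, 90, 140, 220, 350))
  pp0 <- pet_peese(d0)
  expect_gte(pp0$pet_p_one_tailed, 0.05)
  expect_identical(pp0$selected, pp0$pet_estimate)
})

test_that("PET-PEESE rejects degenerate designs", {
  expect_error(pet_peese(toy_studies(c(0.1, 0.2), c(50, 60))), "k >= 3")
  expect_error(pet_peese(homogeneous_studies(5, r = 0.2, n = 100)), "collinear")
})

test_that("conditional p-values are uniform at the generating mean", {
  set.seed(70)
  n <- 120
  v <- rep(1 / (n - 3), 4000)
  mu <- 0.15
  z <- rnorm(4000, mu, sqrt(v))
  crit <- qnorm(0.95) * sqrt(v)
  sig <- z > crit
  q <- (1 - pnorm((z[sig] - mu) / sqrt(v[sig]))) /
    (1 - pnorm((crit[sig] - mu) / sqrt(v[sig])))
  expect_gt(sum(sig), 1500)
  expect_equal(mean(q), 0.5, tolerance = 3 * 0.29 / sqrt(sum(sig)) + 0.01)
  expect_lt(max(q), 1 + 1e-12)
})

test_that("the p-uniform moment sum is monotone and the root matches a grid scan", {
  set.seed(71)
  d <- simulate_meta_data(k = 40, mu_z = 0.25, tau = 0)
  eff <- metarange:::effect_table(d, "fisher_z")
  se <- sqrt(eff$vi)
  crit <- qnorm(0.95) * se
  sig <- eff$yi > crit
  L <- function(mu) {
    -sum(pnorm((eff$yi[sig] - mu) / se[sig], lower.tail = FALSE, log.p = TRUE) -
           pnorm((crit[sig] - mu) / se[sig], lower.tail = FALSE, log.p = TRUE))
  }
  grid <- seq(-0.3, 0.8, by = 0.05)
  vals <- vapply(grid, L, numeric(1))
  expect_true(all(diff(vals) < 0))
  fit <- p_uniform(d)
  expect_equal(L(fit$mu), sum(sig), tolerance = 1e-6)
  # brute-force grid scan around the root
  fine <- seq(fit$mu - 0.05, fit$mu + 0.05, by = 1e-4)
  best <- fine[which.min(abs(vapply(fine, L, numeric(1)) - sum(sig)))]
  expect_equal(fit$mu, best, tolerance = 2e-4)
})

test_that("a single barely-conditioned significant study drives the estimate to it", {
  d <- studies_from_z(c(0.9, 0.01), c(0.01, 0.01))
  fit <- p_uniform(d)
  expect_equal(fit$k_sig, 1L)
  expect_equal(fit$mu, 0.9, tolerance = 0.05)
  none <- p_uniform(studies_from_z(c(0.01, 0.02), c(0.01, 0.01)))
  expect_false(none$applicable)
  expect_true(is.na(none$estimate))
})

test_that("p-uniform overestimates under the heterogeneity it assumes away", {
  set.seed(75)
  ests <- replicate(40, {
    d <- simulate_meta_data(k = 60, mu_z = 0.16, tau = 0.09)
    p_uniform(d)$mu
  })
  expect_gt(mean(ests), 0.16)
})

test_that("the excess-significance statistic follows its closed form", {
  expect_equal(tes_statistic(3, 3, 5)$statistic, 0)
  expect_equal(tes_statistic(3, 3, 5)$p_value, 1)
  A <- 2.25 / 1.5 + 2.25 / 3.5
  ts <- tes_statistic(3, 1.5, 5)
  expect_equal(ts$statistic, A)
  expect_equal(ts$p_value, pchisq(A, 1, lower.tail = FALSE))
  # boundary: all powers 1 and all studies significant
  b <- tes_statistic(5, 5, 5)
  expect_equal(b$p_value, 1)
  expect_error(tes_statistic(6, 3, 5), "observed")
})

test_that("excess significance counts and powers line up on constructed data", {
  # high power, all significant: O = k, E near k, p large
  d <- homogeneous_studies(6, r = 0.5, n = 200)
  ts <- excess_significance(d, rho = 0.5)
  expect_equal(ts$observed_sig, 6L)
  expect_gt(ts$expected_sig, 5.5)
  expect_gt(ts$p_tes, 0.5)
  # rho defaults to the pooled mean
  ts2 <- excess_significance(d)
  expect_equal(ts2$rho, meta_pool(d)$mean)
})

test_that("cumulative meta-analysis sorts by precision and ends at the full pool", {
  d <- toy_studies(c(0.3, 0.1, 0.2, 0.25), c(50, 400, 200, 100))
  cm <- cumulative_by_precision(d)
  expect_equal(cm$id, c("s02", "s03", "s04", "s01"))
  expect_true(all(diff(cm$n_cum) > 0))
  expect_equal(cm$mean[nrow(cm)], meta_pool(d)$mean)
  expect_equal(cm$mean[1], 0.1)
  # identical studies: flat line (ties broken by id)
  dh <- homogeneous_studies(5, r = 0.2)
  cmh <- cumulative_by_precision(dh)
  expect_equal(cmh$mean, rep(0.2, 5))
  expect_equal(cmh$id, sort(dh$id))
  # k = 2: exactly two steps
  d2 <- toy_studies(c(0.1, 0.3), c(300, 50))
  cm2 <- cumulative_by_precision(d2)
  expect_equal(nrow(cm2), 2)
  expect_equal(cm2$mean[2], meta_pool(d2)$mean)
  expect_error(cumulative_by_precision(d2[1, ]), "k >= 2")
})

test_that("suppressed corpora drift upward as small studies enter", {
  set.seed(80)
  drifts <- replicate(20, {
    d <- simulate_meta_data(k = 60, mu_z = 0.10, tau = 0.09,
                            selection = selection_severe())
    cm <- cumulative_by_precision(d)
    q1 <- ceiling(nrow(cm) / 4)
    cm$mean[nrow(cm)] - mean(cm$mean[1:q1])
  })
  expect_gt(mean(drifts), 0)
})

test_that("funnel contours sit at the normal critical half-widths", {
  set.seed(90)
  d <- simulate_meta_data(k = 15, mu_z = 0.1, tau = 0.05)
  fc <- funnel_contours(d)
  b05 <- fc$boundaries[fc$boundaries$level == 0.05, ]
  i <- which.min(abs(b05$se - 0.10))
  expect_equal(b05$upper[i], qnorm(0.975) * b05$se[i])
  expect_equal(b05$upper[i], 1.96 * 0.10, tolerance = 0.01)
  # half-widths widen strictly with SE
  expect_true(all(diff(b05$upper) > 0))
  # |effect|/SE = 1.7 is marginal: p about .089
  dm <- toy_studies(0.17, 101)
  dm$se <- 0.1
  fcm <- funnel_contours(dm)
  expect_equal(as.character(fcm$points$region[1]), "marginal")
  expect_equal(fcm$points$p_two_sided[1], 2 * (1 - pnorm(1.7)), tolerance = 1e-10)
})

test_that("funnel and cumulative autoplots build without error", {
  set.seed(91)
  d <- simulate_meta_data(k = 12, mu_z = 0.15, tau = 0.05)
  expect_s3_class(autoplot(funnel_contours(d)), "ggplot")
  expect_s3_class(autoplot(cumulative_by_precision(d)), "ggplot")
})
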