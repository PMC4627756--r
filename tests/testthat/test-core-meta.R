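test_that("Fisher z transform matches its closed form and round-trips", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(inv_fisher_z(0.549306), 0.5, tolerance = 1e-6)
  expect_identical(inv_fisher_z(0), 0)
  expect_gt(inv_fisher_z(10), 0.999)
  expect_lt(inv_fisher_z(10), 1)
  grid <- seq(-0.99, 0.99, by = 0.03)
  expect_equal(inv_fisher_z(fisher_z(grid)), grid, tolerance = 1e-12)
  expect_equal(inv_fisher_z(fisher_z(0.16)), 0.16, tolerance = 1e-12)
  expect_error(fisher_z(1), "between -1 and 1")
  expect_error(fisher_z(-1.2), "between -1 and 1")
  expect_error(inv_fisher_z(NA_real_), "finite")
})

test_that("effect variances follow the scale conventions", {
  expect_equal(effect_variance(0.2, 103, "fisher_z"), 0.01)
  expect_equal(effect_variance(0, 101, "raw_r"), 0.01)
  expect_equal(effect_variance(0.5, 4, "fisher_z"), 1.0)
  expect_error(effect_variance(0.5, 3, "fisher_z"), "n >= 4")
  # se override column takes precedence over the analytic variance
  d <- toy_studies(c(0.2, 0.3), c(100, 100), se = c(0.05, NA))
  eff <- metarange:::effect_table(d, "fisher_z")
  expect_equal(eff$vi, c(0.05^2, 1 / 97))
})

test_that("pooling reproduces the two-study DerSimonian-Laird hand example", {
  d <- studies_from_z(c(0.2, 0.4), c(0.01, 0.01))
  fe <- meta_pool(d, model = "fixed")
  re <- meta_pool(d, model = "random")
  expect_equal(fe$mu, 0.3)
  expect_equal(re$Q, 2)
  expect_equal(re$tau2, 0.01)
  expect_equal(re$mu, 0.3)
  expect_equal(re$se, 0.1)
  expect_equal(re$mean, tanh(0.3))
})

test_that("identical effects pool to themselves with zero heterogeneity", {
  d <- homogeneous_studies(5, r = 0.3, n = 100)
  fit <- meta_pool(d)
  expect_equal(fit$mean, 0.3)
  expect_equal(fit$Q, 0)
  expect_equal(fit$tau2, 0)
  expect_equal(fit$I2, 0)
  # doubling every n leaves the pooled mean of identical effects unchanged
  d2 <- d
  d2$n <- d$n * 2
  expect_equal(meta_pool(d2)$mean, fit$mean)
  # fixed and random coincide when tau2 = 0
  expect_equal(meta_pool(d, "fixed")$mean, fit$mean)
})

test_that("pooling agrees with metafor's DL implementation", {
  set.seed(101)
  for (i in 1:5) {
    k <- sample(5:40, 1)
    d <- simulate_meta_data(k = k, mu_z = 0.15, tau = 0.08)
    eff <- metarange:::effect_table(d, "fisher_z")
    ref <- metafor::rma(eff$yi, eff$vi, method = "DL")
    fit <- meta_pool(d)
    expect_equal(fit$mu, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(fit$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(fit$Q, ref$QE, tolerance = 1e-10)
    expect_equal(fit$I2, ref$I2, tolerance = 1e-6)
  }
})

test_that("pooled mean stays inside the observed range and CIs shrink with n", {
  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:15, 1)
    d <- toy_studies(runif(k, -0.5, 0.6), sample(20:400, k))
    fit <- meta_pool(d)
    expect_gte(fit$mean, min(d$r) - 1e-12)
    expect_lte(fit$mean, max(d$r) + 1e-12)
  }
  d <- toy_studies(c(0.1, 0.25, 0.4), c(50, 80, 120))
  widths <- vapply(c(1, 2, 4, 8), function(f) {
    d2 <- d
    d2$n <- d$n * f
    fit <- meta_pool(d2, tau2_method = "DL")
    # heterogeneity held fixed: compare on equal tau2 = 0 by using the
    # fixed-effect model, isolating the sampling-variance effect
    fitf <- meta_pool(d2, model = "fixed")
    diff(fitf$ci)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("DL truncation at zero leaves the homogeneous-null median at zero", {
  set.seed(77)
  k <- 10
  v <- rep(1 / 97, k)
  tau2s <- replicate(10000, {
    y <- rnorm(k, 0.15, sqrt(v))
    metarange:::pool_effects(y, v)$tau2
  })
  expect_equal(median(tau2s), 0)
  frac_pos <- mean(tau2s > 0)
  expect_gt(frac_pos, 0.3)
  expect_lt(frac_pos, 0.7)
})

test_that("single-study and empty datasets behave as documented", {
  d1 <- toy_studies(0.2, 100)
  fit <- meta_pool(d1)
  expect_equal(fit$mean, 0.2)
  expect_true(is.na(fit$Q) && is.na(fit$tau2))
  expect_true(all(is.na(fit$pi)))
  expect_error(meta_pool(d1[0, ]), "at least one study")
})

test_that("prediction interval matches its direct t formula", {
  # toy: mean z = 0.16, se = 0.02, tau2 = 0.0064, k = 20
  half <- qt(0.95, df = 18) * sqrt(0.0064 + 0.02^2)
  expected <- tanh(c(0.16 - half, 0.16 + half))
  fake <- structure(list(k = 20, mu = 0.16, se = 0.02, tau2 = 0.0064,
                         scale = "fisher_z"), class = "meta_pool")
  expect_equal(prediction_interval(fake, 0.90), expected)
  # symmetric on the z scale around the pooled mean
  pi_z <- atanh(prediction_interval(fake, 0.90))
  expect_equal(mean(pi_z), 0.16)
  # tau2 = 0, large k: half-width tends to 1.645 * se
  fake2 <- structure(list(k = 2000, mu = 0, se = 0.02, tau2 = 0,
                          scale = "fisher_z"), class = "meta_pool")
  hw <- diff(atanh(prediction_interval(fake2, 0.90))) / 2
  expect_equal(hw, qnorm(0.95) * 0.02, tolerance = 1e-3)
  fake3 <- structure(list(k = 2, mu = 0, se = 0.02, tau2 = 0,
                          scale = "fisher_z"), class = "meta_pool")
  expect_error(prediction_interval(fake3), "k >= 3")
})

test_that("between-group Q behaves at its fixed points and hand example", {
  d <- toy_studies(rep(c(0.2, 0.3), each = 4), rep(c(50, 150), 4),
                   g = rep(c("a", "b"), 4))
  # two identical subgroups -> Q = 0, p = 1
  d_same <- d
  d_same$g <- rep(c("a", "b"), each = 4)
  d_same$r <- rep(c(0.2, 0.3, 0.2, 0.3), 2)
  d_same$n <- rep(c(50, 150, 50, 150), 2)
  q <- subgroup_q(d_same, "g")
  expect_equal(q$Q_between, 0, tolerance = 1e-12)
  expect_equal(q$p_value, 1)
  # hand-built three-group formula check: mu = .1, .2, .3, se = .05 each
  mu <- c(0.1, 0.2, 0.3)
  W <- rep(1 / 0.05^2, 3)
  mu_dot <- weighted.mean(mu, W)
  Q_expected <- sum(W * (mu - mu_dot)^2)
  d3 <- toy_studies(tanh(rep(mu, each = 2)), rep(100, 6),
                    g = rep(c("g1", "g2", "g3"), each = 2),
                    se = rep(0.05 * sqrt(2), 6))
  q3 <- subgroup_q(d3, "g")
  expect_equal(q3$Q_between, Q_expected, tolerance = 1e-10)
  expect_equal(q3$df, 2)
  expect_error(subgroup_q(toy_studies(0.1, 50, g = "only"), "g"), "two non-empty")
})

test_that("validation reports every violation with its row", {
  bad <- tibble::tibble(id = c("a", "b", "b"), r = c(0.2, 1.2, 0.3), n = c(50, 60, 3))
  err <- tryCatch(validate_meta_data(bad), error = function(e) conditionMessage(e))
  expect_match(err, "row\\(s\\) 2")
  expect_match(err, "row\\(s\\) 3")
  expect_match(err, "duplicate study id\\(s\\): b")
  expect_error(validate_meta_data(tibble::tibble(id = "a", r = 0.2)), "Missing required")
})

test_that("CSV round trip preserves the study table", {
  d <- toy_studies(c(0.1, 0.2, 0.3), c(50, 60, 70), source = c("j", "j", "n"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_meta_csv(d, path)
  back <- read_meta_csv(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$r, d$r)
  expect_equal(back$source, d$source)
  expect_equal(moderator_columns(back), "source")
})
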