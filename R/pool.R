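# Inverse-variance pooling on a (yi, vi) vector pair. Heterogeneity uses
# the DerSimonian-Laird moment estimator by default (matching the
# Hedges-Olkin tradition and the CMA default); "REML" delegates the tau2
# step to metafor. k = 1 returns the single effect with heterogeneity
# fields set to NA.
pool_effects <- function(yi, vi, model = c("random", "fixed"),
                         tau2_method = c("DL", "REML")) {
  model <- match.arg(model)
  tau2_method <- match.arg(tau2_method)
  k <- length(yi)
  if (k < 1) abort("Cannot pool an empty set of effects.")
  if (any(vi <= 0) || any(!is.finite(vi))) abort("All sampling variances must be positive and finite.")
  w <- 1 / vi
  mu_fe <- sum(w * yi) / sum(w)
  se_fe <- sqrt(1 / sum(w))
  if (k == 1) {
    return(list(
      k = 1L, model = model, mu = yi, se = sqrt(vi), mu_fe = mu_fe, se_fe = se_fe,
      Q = NA_real_, df = 0L, I2 = NA_real_, tau2 = NA_real_
    ))
  }
  Q <- sum(w * (yi - mu_fe)^2)
  df <- k - 1L
  tau2 <- switch(tau2_method,
    DL = max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w))),
    REML = metafor::rma(yi, vi, method = "REML")$tau2
  )
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  if (model == "random") {
    wr <- 1 / (vi + tau2)
    mu <- sum(wr * yi) / sum(wr)
    se <- sqrt(1 / sum(wr))
  } else {
    mu <- mu_fe
    se <- se_fe
  }
  list(k = k, model = model, mu = mu, se = se, mu_fe = mu_fe, se_fe = se_fe,
       Q = Q, df = df, I2 = I2, tau2 = tau2)
}

#' Pool correlations under a fixed- or random-effects model
#'
#' Inverse-variance pooling of study correlations, by default on the
#' Fisher z scale with the DerSimonian-Laird between-study variance
#' estimator. The pooled mean, confidence interval and (for k >= 3)
#' prediction interval are back-transformed to the correlation metric;
#' heterogeneity statistics (Q, I-squared, tau-squared) are reported on
#' the analysis scale.
#'
#' The 100*`pi_level`% prediction interval is
#' `mu +/- t(k - 2) * sqrt(tau2 + se^2)` on the analysis scale, the usual
#' t-based form for the range of true effects in a new study.
#'
#' @param data A study table (see [validate_meta_data()]).
#' @param model `"random"` (default) or `"fixed"`.
#' @param scale Analysis scale, `"fisher_z"` (default) or `"raw_r"`.
#' @param tau2_method `"DL"` (DerSimonian-Laird, default) or `"REML"`.
#' @param level Confidence level for the mean (default 0.95).
#' @param pi_level Prediction-interval level (default 0.90).
#' @return An object of class `meta_pool` with `tidy()`, `glance()` and
#'   `print()` methods. Key fields: `mean` (pooled correlation), `ci`,
#'   `pi`, `Q`, `df`, `I2`, `tau2`, `tau`, plus `mu`/`se` on the
#'   analysis scale.
#' @examples
#' d <- tibble::tibble(id = paste0("s", 1:5), r = c(.1, .2, .15, .3, .25),
#'                     n = c(50, 80, 120, 60, 200))
#' fit <- meta_pool(d)
#' glance(fit)
#' @export
meta_pool <- function(data, model = c("random", "fixed"),
                      scale = c("fisher_z", "raw_r"),
                      tau2_method = c("DL", "REML"),
                      level = 0.95, pi_level = 0.90) {
  model <- match.arg(model)
  scale <- match.arg(scale)
  tau2_method <- match.arg(tau2_method)
  eff <- effect_table(data, scale)
  res <- pool_effects(eff$yi, eff$vi, model, tau2_method)
  zcrit <- qnorm((1 + level) / 2)
  ci <- c(res$mu - zcrit * res$se, res$mu + zcrit * res$se)
  pi <- c(NA_real_, NA_real_)
  if (res$k >= 3 && is.finite(res$tau2)) {
    tcrit <- qt((1 + pi_level) / 2, df = res$k - 2)
    half <- tcrit * sqrt(res$tau2 + res$se^2)
    pi <- c(res$mu - half, res$mu + half)
  }
  wts <- if (model == "random" && res$k > 1) 1 / (eff$vi + res$tau2) else 1 / eff$vi
  out <- list(
    k = res$k, model = model, scale = scale, tau2_method = tau2_method,
    level = level, pi_level = pi_level,
    mean = back_transform(res$mu, scale),
    ci = back_transform(ci, scale),
    pi = back_transform(pi, scale),
    mean_fe = back_transform(res$mu_fe, scale),
    mu = res$mu, se = res$se, mu_fe = res$mu_fe, se_fe = res$se_fe,
    Q = res$Q, df = res$df, I2 = res$I2,
    tau2 = res$tau2, tau = sqrt(pmax(res$tau2, 0)),
    studies = tibble::tibble(eff, weight_pct = 100 * wts / sum(wts))
  )
  structure(out, class = "meta_pool")
}

#' @export
print.meta_pool <- function(x, digits = 3, ...) {
  cat(sprintf("%s-effects pooled correlation (%s scale, %s tau2)\n",
              x$model, x$scale, x$tau2_method))
  cat(sprintf("k = %d, mean r = %.*f [%.*f, %.*f]\n",
              x$k, digits, x$mean, digits, x$ci[1], digits, x$ci[2]))
  if (all(is.finite(x$pi))) {
    cat(sprintf("%d%% prediction interval: [%.*f, %.*f]\n",
                round(100 * x$pi_level), digits, x$pi[1], digits, x$pi[2]))
  }
  if (is.finite(x$Q)) {
    cat(sprintf("Q = %.*f (df = %d), I2 = %.1f%%, tau = %.*f\n",
                digits, x$Q, x$df, x$I2, digits, x$tau))
  }
  invisible(x)
}

#' @export
glance.meta_pool <- function(x, ...) {
  tibble::tibble(
    k = x$k, model = x$model, scale = x$scale,
    mean = x$mean, ci_lower = x$ci[1], ci_upper = x$ci[2],
    pi_lower = x$pi[1], pi_upper = x$pi[2],
    mean_fe = x$mean_fe, se = x$se,
    Q = x$Q, df = x$df, I2 = x$I2, tau2 = x$tau2, tau = x$tau
  )
}

#' @export
tidy.meta_pool <- function(x, ...) {
  x$studies
}

#' Prediction interval of a pooled result
#'
#' Interval expected to contain the true effect of a new study under the
#' random-effects model: `mu +/- t(k - 2) * sqrt(tau2 + se^2)` on the
#' analysis scale, back-transformed to the correlation metric.
#'
#' @param pooled A [meta_pool()] fit with `k >= 3`.
#' @param level Interval level (default 0.90).
#' @return Length-2 numeric vector (lower, upper) on the r scale.
#' @export
prediction_interval <- function(pooled, level = 0.90) {
  if (!inherits(pooled, "meta_pool")) abort("`pooled` must be a meta_pool object.")
  if (pooled$k < 3) abort("A prediction interval requires k >= 3 studies.")
  if (!is.finite(pooled$tau2)) abort("Prediction interval undefined: tau2 unavailable.")
  tcrit <- qt((1 + level) / 2, df = pooled$k - 2)
  half <- tcrit * sqrt(pooled$tau2 + pooled$se^2)
  back_transform(c(pooled$mu - half, pooled$mu + half), pooled$scale)
}

#' Between-group heterogeneity test
#'
#' Tests whether random-effects subgroup means differ, using the
#' between-group Q statistic: `Q_b = sum_j W_j (mu_j - mu_.)^2`, where
#' `mu_j` are the subgroup random-effects means on the analysis scale,
#' `W_j = 1/se_j^2`, and `mu_.` is their W-weighted mean. `Q_b` is
#' referred to a chi-square distribution with (number of groups - 1)
#' degrees of freedom.
#'
#' @param data A study table.
#' @param moderator Name of the moderator column defining the groups.
#' @param scale Analysis scale (default Fisher z).
#' @param tau2_method Between-study variance estimator per subgroup.
#' @return A one-row tibble: `moderator`, `n_groups`, `Q_between`, `df`,
#'   `p_value`.
#' @export
subgroup_q <- function(data, moderator, scale = c("fisher_z", "raw_r"),
                       tau2_method = c("DL", "REML")) {
  scale <- match.arg(scale)
  tau2_method <- match.arg(tau2_method)
  check_meta_data(data)
  if (!moderator %in% names(data)) {
    abort(paste0("Moderator column not found: ", moderator))
  }
  groups <- split(data, as.character(data[[moderator]]))
  if (length(groups) < 2) abort("`subgroup_q()` needs at least two non-empty groups.")
  fits <- lapply(groups, function(g) {
    eff <- effect_table(g, scale)
    pool_effects(eff$yi, eff$vi, "random", tau2_method)
  })
  mu <- vapply(fits, `[[`, numeric(1), "mu")
  W <- 1 / vapply(fits, `[[`, numeric(1), "se")^2
  mu_dot <- sum(W * mu) / sum(W)
  Qb <- sum(W * (mu - mu_dot)^2)
  df <- length(groups) - 1L
  tibble::tibble(
    moderator = moderator,
    n_groups = length(groups),
    Q_between = Qb,
    df = df,
    p_value = pchisq(Qb, df, lower.tail = FALSE)
  )
}
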