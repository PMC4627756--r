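#' Vevea-Woods a-priori step-function weights
#'
#' The one-tailed p-value cut-points and fixed retention weights used to
#' model moderate and severe publication-bias selection. The first
#' interval (p <= .005) always has weight 1; weights decline as results
#' become less significant. `vevea_woods_steps()` returns the fourteen
#' ascending cut-points (ending at 1); `vevea_woods_weights()` the
#' matching weight vector.
#'
#' @param severity `"moderate"` or `"severe"`.
#' @param tails `"one"` (default) or `"two"` tailed weight functions.
#' @return Numeric vector of length 14.
#' @export
vevea_woods_steps <- function() {
  c(0.005, 0.010, 0.050, 0.100, 0.250, 0.350, 0.500,
    0.650, 0.750, 0.900, 0.950, 0.990, 0.995, 1.000)
}

#' @rdname vevea_woods_steps
#' @export
vevea_woods_weights <- function(severity = c("moderate", "severe"),
                                tails = c("one", "two")) {
  severity <- match.arg(severity)
  tails <- match.arg(tails)
  if (tails == "one") {
    switch(severity,
      moderate = c(1, .99, .95, .80, .75, .65, .60, .55, .50, .50, .50, .50, .50, .50),
      severe   = c(1, .99, .90, .75, .60, .50, .25, .10, .10, .10, .10, .10, .10, .10)
    )
  } else {
    switch(severity,
      moderate = c(1, .99, .95, .90, .80, .75, .60, .60, .75, .80, .90, .95, .99, 1),
      severe   = c(1, .99, .90, .75, .60, .50, .25, .25, .50, .60, .75, .90, .99, 1)
    )
  }
}

# Interval index of one-tailed p-values given ascending cut-points.
p_interval_index <- function(p, steps) {
  as.integer(cut(p, breaks = c(0, steps), include.lowest = TRUE))
}

#' A-priori step-function selection model
#'
#' Maximum-likelihood estimation of the mean effect and between-study
#' variance on the Fisher z scale under a *fixed* one-tailed step
#' weight function w(p): the probability that a study with one-tailed
#' p-value in a given interval is observed. Each study contributes
#' `log w(p_i) + log phi((z_i - mu)/s_i) - log sum_j w_j P_ij` to the
#' log-likelihood, where `s_i^2 = v_i + tau2` and `P_ij` is the
#' probability mass of interval j for study i. With all weights equal to
#' one the model reduces to ordinary random-effects ML.
#'
#' Defaults use the Vevea-Woods moderate or severe one-tailed weights
#' ([vevea_woods_weights()]); both the cut-points and weights can be
#' overridden.
#'
#' @param data A study table with at least 3 studies spanning at least
#'   two p-value intervals.
#' @param severity `"moderate"` or `"severe"` preset.
#' @param steps,weights Optional custom cut-points / weights.
#' @param scale Analysis scale (Fisher z by default, as is conventional
#'   for these models on correlations).
#' @return An object of class `selection_model` with fields
#'   `adjusted_mean` (back-transformed), `mu`, `tau2`
#'   (`variance_component`), `loglik`, `converged`, `applicable`.
#' @export
selection_model <- function(data, severity = c("moderate", "severe"),
                            steps = NULL, weights = NULL,
                            scale = c("fisher_z", "raw_r")) {
  severity <- match.arg(severity)
  scale <- match.arg(scale)
  steps <- steps %||% vevea_woods_steps()
  weights <- weights %||% vevea_woods_weights(severity)
  if (length(steps) != length(weights)) abort("`steps` and `weights` must have equal length.")
  if (is.unsorted(steps, strictly = TRUE) || tail(steps, 1) != 1) {
    abort("`steps` must be strictly ascending and end at 1.")
  }
  if (weights[1] != 1 || any(weights <= 0) || any(weights > 1)) {
    abort("`weights` must lie in (0, 1] with the first interval weight equal to 1.")
  }
  eff <- effect_table(data, scale)
  k <- nrow(eff)
  if (k < 3) abort("Selection models require k >= 3 studies.")
  p_one <- pnorm(eff$yi / sqrt(eff$vi), lower.tail = FALSE)
  idx <- p_interval_index(p_one, steps)
  if (length(unique(idx)) < 2) {
    abort("All studies fall in a single p-value interval: the step weights are non-identifying.")
  }
  # z-space thresholds per study: p <= steps[j] iff z >= b[, j]
  b <- outer(sqrt(eff$vi), qnorm(1 - steps))
  upper <- cbind(Inf, b[, -ncol(b), drop = FALSE])
  log_w_obs <- sum(log(weights[idx]))
  nll <- function(par) {
    mu <- par[1]
    tau2 <- exp(par[2])
    s <- sqrt(eff$vi + tau2)
    P <- pnorm((upper - mu) / s) - pnorm((b - mu) / s)
    D <- as.vector(P %*% weights)
    if (any(D <= 0) || any(!is.finite(D))) return(1e10)
    -(log_w_obs + sum(dnorm(eff$yi, mu, s, log = TRUE)) - sum(log(D)))
  }
  start <- pool_effects(eff$yi, eff$vi, "random", "DL")
  fit <- tryCatch(
    nlminb(c(start$mu, log(max(start$tau2, 1e-4))), nll,
           lower = c(-5, -25), upper = c(5, 2)),
    error = function(e) NULL
  )
  converged <- !is.null(fit) && fit$convergence == 0 && is.finite(fit$objective)
  mu_hat <- if (converged) fit$par[1] else NA_real_
  tau2_hat <- if (converged) exp(fit$par[2]) else NA_real_
  # "not applicable" mirrors reporting conventions for nonsensical
  # variance components: a between-study variance this large on the z
  # scale cannot arise from correlation data.
  applicable <- converged && is.finite(tau2_hat) && tau2_hat < 1
  structure(list(
    severity = severity, k = k, scale = scale,
    steps = steps, weights = weights,
    adjusted_mean = if (applicable) back_transform(mu_hat, scale) else NA_real_,
    mu = mu_hat,
    variance_component = tau2_hat,
    loglik = if (converged) -fit$objective else NA_real_,
    converged = converged,
    applicable = applicable
  ), class = "selection_model")
}

#' @export
print.selection_model <- function(x, digits = 3, ...) {
  cat(sprintf("One-tailed %s selection model (k = %d)\n", x$severity, x$k))
  if (x$applicable) {
    cat(sprintf("adjusted mean r = %.*f (tau2 = %.*f, logLik = %.2f)\n",
                digits, x$adjusted_mean, digits, x$variance_component, x$loglik))
  } else {
    cat("estimate not applicable (non-convergence or nonsensical variance component)\n")
  }
  invisible(x)
}

#' @export
glance.selection_model <- function(x, ...) {
  tibble::tibble(
    severity = x$severity, adjusted_mean = x$adjusted_mean,
    variance_component = x$variance_component, loglik = x$loglik,
    converged = x$converged, applicable = x$applicable
  )
}
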