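#' Chi-square statistic for the test of excess significance
#'
#' Given the observed count `observed` of significant studies, the
#' power-expected count `expected`, and the number of studies `k`, the
#' statistic is `A = (O - E)^2 / E + (O - E)^2 / (k - E)` referred to a
#' one-degree chi-square. `O == E` yields `A = 0` and `p = 1`; at the
#' boundaries `E = 0` or `E = k` the statistic is undefined and the
#' boundary probability (1 when `O` equals the boundary value, 0
#' otherwise) is reported.
#'
#' @param observed Observed count of significant studies.
#' @param expected Expected count (sum of per-study powers).
#' @param k Number of studies.
#' @return A list with `statistic` and `p_value`.
#' @export
tes_statistic <- function(observed, expected, k) {
  if (observed < 0 || observed > k) abort("`observed` must lie in [0, k].")
  if (expected < 0 || expected > k) abort("`expected` must lie in [0, k].")
  if (expected <= 0 || expected >= k) {
    boundary <- if (expected <= 0) 0 else k
    return(list(statistic = NA_real_, p_value = as.numeric(observed == boundary)))
  }
  A <- (observed - expected)^2 / expected + (observed - expected)^2 / (k - expected)
  list(statistic = A, p_value = pchisq(A, df = 1, lower.tail = FALSE))
}

#' Test of excess significance
#'
#' Compares the observed number of studies reaching two-sided
#' significance with the number expected from the studies' power to
#' detect an assumed population correlation (by default, the
#' random-effects pooled mean of the dataset itself). A small probability
#' (conventionally below .10) indicates more significant findings than
#' the evidence base should be able to produce, i.e. a non-credible set.
#'
#' Power and significance are evaluated on the Fisher z scale with a
#' two-sided level `alpha` for both the observed count and the power
#' calculation.
#'
#' @param data A study table.
#' @param rho Assumed population correlation; `NULL` (default) uses the
#'   random-effects pooled mean.
#' @param alpha Two-sided significance level (default 0.05).
#' @return An object of class `tes` with fields `observed_sig`,
#'   `expected_sig`, `statistic`, `p_tes`, `rho`.
#' @export
excess_significance <- function(data, rho = NULL, alpha = 0.05) {
  eff <- effect_table(data, "fisher_z")
  k <- nrow(eff)
  if (is.null(rho)) {
    rho <- back_transform(pool_effects(eff$yi, eff$vi, "random", "DL")$mu, "fisher_z")
  }
  theta <- atanh(rho)
  se <- sqrt(eff$vi)
  zcrit <- qnorm(1 - alpha / 2)
  ncp <- theta / se
  power <- pnorm(zcrit - ncp, lower.tail = FALSE) + pnorm(-zcrit - ncp)
  observed <- sum(abs(eff$yi) / se > zcrit)
  expected <- sum(power)
  ts <- tes_statistic(observed, expected, k)
  structure(list(
    k = k, rho = rho, alpha = alpha,
    observed_sig = as.integer(observed), expected_sig = expected,
    statistic = ts$statistic, p_tes = ts$p_value,
    power = power
  ), class = "tes")
}

#' @export
print.tes <- function(x, digits = 3, ...) {
  cat(sprintf("Test of excess significance (rho = %.*f): O = %d, E = %.2f, P-TES = %.3f\n",
              digits, x$rho, x$observed_sig, x$expected_sig, x$p_tes))
  invisible(x)
}

#' @export
glance.tes <- function(x, ...) {
  tibble::tibble(
    observed_sig = x$observed_sig, expected_sig = x$expected_sig,
    statistic = x$statistic, p_tes = x$p_tes, rho = x$rho
  )
}
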