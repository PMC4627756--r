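#' PET-PEESE precision-based meta-regression
#'
#' PET regresses the raw correlations on their standard errors by
#' weighted least squares (weights `1/SE^2`); its intercept estimates the
#' effect of a hypothetical infinitely precise study. PEESE replaces the
#' standard error with the sampling variance as predictor. Following the
#' conditional rule, the PEESE intercept is the adjusted estimate when
#' the one-tailed PET intercept test (`H1: intercept > 0`) is significant
#' at `alpha`, and the PET intercept otherwise.
#'
#' Both regressions run on untransformed correlations, the conventional
#' metric for this procedure. Standard errors are evaluated at the pooled
#' correlation, `SE_i = (1 - rbar^2)/sqrt(n_i - 1)`, rather than at each
#' study's own estimate: a study's reported effect enters its analytic
#' standard error, and that mechanical coupling alone tilts an
#' effect-on-SE regression. Decoupling the two (the usual practice in
#' this literature's psychometric tradition) leaves the regressor a pure
#' function of sample size. An `se` column overrides this choice.
#'
#' @param data A study table with at least 3 studies whose standard
#'   errors are not all equal.
#' @param alpha One-tailed significance level for the PET intercept test
#'   (default 0.05).
#' @return An object of class `pet_peese` with fields `pet_estimate`,
#'   `pet_p_one_tailed`, `peese_estimate`, `selected`, `slope_pet`,
#'   `slope_peese`.
#' @export
pet_peese <- function(data, alpha = 0.05) {
  eff <- effect_table(data, "raw_r")
  k <- nrow(eff)
  if (k < 3) abort("PET-PEESE requires k >= 3 studies.")
  rbar <- meta_pool(data)$mean
  vi <- (1 - rbar^2)^2 / (data$n - 1)
  if ("se" %in% names(data)) {
    ov <- !is.na(data$se)
    vi[ov] <- data$se[ov]^2
  }
  se <- sqrt(vi)
  if (max(se) - min(se) < .Machine$double.eps^0.5) {
    abort("All standard errors are equal: the PET regression is collinear.")
  }
  df <- data.frame(r = eff$yi, se = se)
  pet <- lm(r ~ se, data = df, weights = 1 / se^2)
  peese <- lm(r ~ I(se^2), data = df, weights = 1 / se^2)
  ct <- summary(pet)$coefficients
  pet_est <- unname(coef(pet)[1])
  peese_est <- unname(coef(peese)[1])
  p_one <- unname(pt(ct[1, "t value"], df = k - 2, lower.tail = FALSE))
  structure(list(
    k = k, alpha = alpha,
    pet_estimate = pet_est,
    pet_p_one_tailed = p_one,
    peese_estimate = peese_est,
    selected = if (p_one < alpha) peese_est else pet_est,
    pet_significant = p_one < alpha,
    slope_pet = unname(coef(pet)[2]),
    slope_peese = unname(coef(peese)[2])
  ), class = "pet_peese")
}

#' @export
print.pet_peese <- function(x, digits = 3, ...) {
  cat(sprintf("PET intercept = %.*f (one-tailed p = %.3f); PEESE intercept = %.*f\n",
              digits, x$pet_estimate, x$pet_p_one_tailed, digits, x$peese_estimate))
  cat(sprintf("selected adjusted mean: %.*f (%s)\n", digits, x$selected,
              if (x$pet_significant) "PEESE, PET significant" else "PET"))
  invisible(x)
}

#' @export
glance.pet_peese <- function(x, ...) {
  tibble::tibble(
    pet_estimate = x$pet_estimate, pet_p_one_tailed = x$pet_p_one_tailed,
    peese_estimate = x$peese_estimate, selected = x$selected,
    slope_pet = x$slope_pet, slope_peese = x$slope_peese
  )
}
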