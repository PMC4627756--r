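#' Run the full publication-bias battery on one distribution
#'
#' Applies, in one call, the sensitivity battery this package is built
#' around: random- and fixed-effects pooling with prediction interval,
#' one-sample-removed analysis, trim-and-fill, the moderate and severe
#' a-priori selection models, the test of excess significance,
#' PET-PEESE, p-uniform, cumulative meta-analysis by precision, and
#' funnel contour data. Scale conventions follow the battery's
#' standard practice: pooling, one-sample-removed, trim-and-fill,
#' selection models and p-uniform on Fisher z; PET-PEESE and funnel
#' coordinates on raw correlations.
#'
#' Bias procedures are only run when the distribution holds at least
#' `min_k` studies (default 10); smaller distributions keep their pooled
#' and one-sample-removed statistics, and the skipped methods are
#' recorded in `$skipped_reasons`. Individual method failures (e.g. a
#' non-converging selection model) are caught and reported as
#' not-applicable rather than aborting the battery.
#'
#' @param data A study table.
#' @param label Distribution label used in reports.
#' @param min_k Minimum number of studies for bias procedures.
#' @param alpha Significance level shared by the battery's tests.
#' @param tau2_method Between-study variance estimator for pooling.
#' @return An object of class `bias_battery` holding the individual
#'   result objects; `glance()` flattens it into the one-row,
#'   report-shaped tibble.
#' @export
bias_battery <- function(data, label = "distribution", min_k = 10,
                         alpha = 0.05, tau2_method = c("DL", "REML")) {
  tau2_method <- match.arg(tau2_method)
  check_meta_data(data)
  k <- nrow(data)
  skipped <- character()
  safe <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      skipped <<- c(skipped, paste0(what, ": ", conditionMessage(e)))
      NULL
    })
  }
  pool_re <- meta_pool(data, "random", "fisher_z", tau2_method)
  pool_fe <- meta_pool(data, "fixed", "fisher_z", tau2_method)
  osr <- if (k >= 3) safe("one_sample_removed", one_sample_removed(data, tau2_method = tau2_method)) else {
    skipped <- c(skipped, "one_sample_removed: requires k >= 3")
    NULL
  }
  run_bias <- k >= min_k
  if (!run_bias) {
    skipped <- c(skipped, sprintf(
      "bias battery skipped: k = %d below the minimum of %d studies", k, min_k))
  }
  out <- list(
    label = label, k = k, min_k = min_k, alpha = alpha,
    bias_assessed = run_bias,
    pool_re = pool_re, pool_fe = pool_fe, osr = osr,
    trim_fill = if (run_bias) safe("trim_and_fill", trim_and_fill(data)) else NULL,
    sm_moderate = if (run_bias) safe("selection_model(moderate)", selection_model(data, "moderate")) else NULL,
    sm_severe = if (run_bias) safe("selection_model(severe)", selection_model(data, "severe")) else NULL,
    tes = if (run_bias) safe("excess_significance", excess_significance(data, alpha = alpha)) else NULL,
    pet_peese = if (run_bias) safe("pet_peese", pet_peese(data, alpha = alpha)) else NULL,
    p_uniform = if (run_bias) safe("p_uniform", p_uniform(data, alpha = alpha)) else NULL,
    cumulative = if (run_bias) safe("cumulative_by_precision", cumulative_by_precision(data)) else NULL,
    funnel = if (run_bias) safe("funnel_contours", funnel_contours(data)) else NULL,
    skipped_reasons = skipped
  )
  structure(out, class = "bias_battery")
}

# Registry of the battery's bias procedures; the report schema must
# contain every one of them exactly once per distribution.
battery_method_registry <- function() {
  c("trim_fill", "sm_moderate", "sm_severe", "tes", "pet_peese",
    "p_uniform", "cumulative")
}

na_if_null <- function(x, field) {
  if (is.null(x)) NA_real_ else as.numeric(x[[field]])
}

#' @export
glance.bias_battery <- function(x, ...) {
  sm_val <- function(sm, field) {
    if (is.null(sm) || !isTRUE(sm$applicable)) NA_real_ else as.numeric(sm[[field]])
  }
  tf <- x$trim_fill
  pp <- x$pet_peese
  pu <- if (!is.null(x$p_uniform) && isTRUE(x$p_uniform$applicable)) x$p_uniform else NULL
  tibble::tibble(
    distribution = x$label,
    k = x$k,
    re_mean = x$pool_re$mean,
    re_ci_lower = x$pool_re$ci[1], re_ci_upper = x$pool_re$ci[2],
    pi_lower = x$pool_re$pi[1], pi_upper = x$pool_re$pi[2],
    Q = x$pool_re$Q, I2 = x$pool_re$I2, tau = x$pool_re$tau,
    osr_min = if (is.null(x$osr)) NA_real_ else x$osr$min,
    osr_median = if (is.null(x$osr)) NA_real_ else x$osr$median,
    osr_max = if (is.null(x$osr)) NA_real_ else x$osr$max,
    fe_mean = x$pool_fe$mean,
    fps = if (is.null(tf) || tf$k0 == 0) "" else toupper(substr(tf$side, 1, 1)),
    ik = if (is.null(tf)) NA_integer_ else tf$k0,
    tf_mean = na_if_null(tf, "adjusted_mean"),
    tf_ci_lower = if (is.null(tf)) NA_real_ else tf$adjusted_ci[1],
    tf_ci_upper = if (is.null(tf)) NA_real_ else tf$adjusted_ci[2],
    sm_moderate = sm_val(x$sm_moderate, "adjusted_mean"),
    sm_moderate_var = sm_val(x$sm_moderate, "variance_component"),
    sm_severe = sm_val(x$sm_severe, "adjusted_mean"),
    sm_severe_var = sm_val(x$sm_severe, "variance_component"),
    p_tes = na_if_null(x$tes, "p_tes"),
    pet = na_if_null(pp, "pet_estimate"),
    pet_p = na_if_null(pp, "pet_p_one_tailed"),
    peese = na_if_null(pp, "peese_estimate"),
    pet_peese = na_if_null(pp, "selected"),
    p_uniform = na_if_null(pu, "estimate"),
    p_uniform_ci_lower = if (is.null(pu)) NA_real_ else pu$ci[1],
    p_uniform_ci_upper = if (is.null(pu)) NA_real_ else pu$ci[2],
    bias_assessed = x$bias_assessed
  )
}

#' @export
print.bias_battery <- function(x, ...) {
  cat(sprintf("Publication-bias battery for '%s' (k = %d)\n", x$label, x$k))
  print(glance(x), width = Inf)
  if (length(x$skipped_reasons) > 0) {
    cat("skipped:\n")
    cat(paste0("  - ", x$skipped_reasons, collapse = "\n"), "\n")
  }
  invisible(x)
}
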