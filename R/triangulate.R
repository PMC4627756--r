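#' Collect the adjusted-estimate set from a battery result
#'
#' The triangulation layer works on the set of mean-validity estimates a
#' battery produces: the random-effects mean, the fixed-effects mean,
#' the one-sample-removed minimum/median/maximum, the trim-and-fill
#' adjusted mean, the moderate and severe selection-model means, and the
#' PET-PEESE selected estimate. p-uniform joins only on request (its
#' estimates behave poorly under heterogeneity and are excluded from the
#' default set); the test of excess significance never joins, being a
#' probability rather than an effect size. Not-applicable members are
#' kept as `NA` and ignored by the range scans.
#'
#' @param x A [bias_battery()] object or its `glance()` row.
#' @param include_p_uniform Add the p-uniform estimate to the set?
#' @return A named numeric vector of class `estimate_set`; the
#'   `re_mean` member is always present.
#' @export
collect_estimates <- function(x, include_p_uniform = FALSE) {
  row <- if (inherits(x, "bias_battery")) glance(x) else tibble::as_tibble(x)
  if (nrow(row) != 1) abort("`x` must describe exactly one distribution.")
  if (!"re_mean" %in% names(row) || is.na(row$re_mean)) {
    abort("The estimate set requires a non-missing `re_mean`.")
  }
  grab <- function(col) if (col %in% names(row)) as.numeric(row[[col]]) else NA_real_
  est <- c(
    re_mean = grab("re_mean"),
    fe_mean = grab("fe_mean"),
    osr_min = grab("osr_min"),
    osr_median = grab("osr_median"),
    osr_max = grab("osr_max"),
    tf_mean = grab("tf_mean"),
    sm_moderate = grab("sm_moderate"),
    sm_severe = grab("sm_severe"),
    pet_peese = grab("pet_peese")
  )
  if (include_p_uniform) est <- c(est, p_uniform = grab("p_uniform"))
  structure(est, class = "estimate_set")
}

#' Classify a relative range percentage
#'
#' Practical-difference bands for the relative (percentage) range of
#' adjusted estimates: below 20% is negligible, 20% up to (but not
#' including) 40% is moderate, and 40% or more is large.
#'
#' @param pct Non-negative percentage(s).
#' @return Ordered factor with levels negligible < moderate < large.
#' @export
range_classify <- function(pct) {
  if (any(is.na(pct)) || any(pct < 0)) abort("`pct` must be non-negative.")
  cls <- ifelse(pct >= 40, "large", ifelse(pct >= 20, "moderate", "negligible"))
  factor(cls, levels = c("negligible", "moderate", "large"), ordered = TRUE)
}

#' Conclusion string for a pair of range classes
#'
#' Equal classes give `"<Class> difference"`; unequal classes give
#' `"<Milder> to <severer> difference"`.
#'
#' @param class_bre,class_mre Classifications as produced by
#'   [range_classify()] (or their labels).
#' @return Character scalar.
#' @export
range_conclusion <- function(class_bre, class_mre) {
  lv <- c("negligible", "moderate", "large")
  a <- as.character(class_bre)
  b <- as.character(class_mre)
  if (!a %in% lv || !b %in% lv) abort("Classes must be negligible, moderate or large.")
  cap <- function(s) paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
  if (a == b) return(paste(cap(a), "difference"))
  ord <- lv[sort(match(c(a, b), lv))]
  paste(cap(ord[1]), "to", ord[2], "difference")
}

#' Baseline and maximum range statistics of an estimate set
#'
#' Condenses a set of adjusted mean-validity estimates into the two
#' range statistics used to judge robustness:
#' the baseline range estimate (BRE) is the absolute difference between
#' the random-effects mean and the member farthest from it; the maximum
#' range estimate (MRE) is the spread between the lowest and highest
#' members. Relative ranges express these as percentages of the
#' random-effects mean (the base, 100%).
#'
#' Estimates are rounded to `digits` decimals before the ranges and
#' percentages are formed, matching how such tables are reported;
#' the unrounded percentages are retained alongside. Classification uses
#' the integer-rounded percentages (see [range_classify()]).
#'
#' @param x An `estimate_set`, a [bias_battery()] object, or a data
#'   frame of battery `glance()` rows (one triangulation per row).
#' @param include_p_uniform Passed to [collect_estimates()] where
#'   applicable.
#' @param digits Reporting precision of the estimates (default 2).
#' @param ... Unused.
#' @return A tibble with one row per distribution: `lowest`, `re_mean`,
#'   `highest`, `bre_abs`, `bre_pct` (integer), `bre_pct_raw`,
#'   `bre_class`, `mre_abs`, `mre_pct`, `mre_pct_raw`, `mre_class`,
#'   `conclusion`.
#' @examples
#' est <- structure(c(re_mean = .16, tf_mean = .13, sm_severe = .12,
#'                    osr_max = .16), class = "estimate_set")
#' triangulate(est)
#' @export
triangulate <- function(x, ...) UseMethod("triangulate")

#' @rdname triangulate
#' @export
triangulate.estimate_set <- function(x, digits = 2, ...) {
  vals <- round(unclass(x), digits)
  re <- vals[["re_mean"]]
  present <- vals[!is.na(vals)]
  if (length(present) < 2) abort("Range statistics need at least 2 present estimates.")
  if (re == 0) abort("Relative ranges are undefined when the random-effects mean is 0.")
  lowest <- min(present)
  highest <- max(present)
  bre_abs <- max(abs(re - lowest), abs(highest - re))
  mre_abs <- highest - lowest
  bre_pct_raw <- 100 * bre_abs / re
  mre_pct_raw <- 100 * mre_abs / re
  bre_pct <- round(bre_pct_raw)
  mre_pct <- round(mre_pct_raw)
  cls_b <- range_classify(bre_pct)
  cls_m <- range_classify(mre_pct)
  tibble::tibble(
    lowest = lowest, re_mean = re, highest = highest,
    bre_abs = bre_abs, bre_pct = bre_pct, bre_pct_raw = bre_pct_raw,
    bre_class = as.character(cls_b),
    mre_abs = mre_abs, mre_pct = mre_pct, mre_pct_raw = mre_pct_raw,
    mre_class = as.character(cls_m),
    conclusion = range_conclusion(cls_b, cls_m)
  )
}

#' @rdname triangulate
#' @export
triangulate.bias_battery <- function(x, include_p_uniform = FALSE, digits = 2, ...) {
  out <- triangulate(collect_estimates(x, include_p_uniform), digits = digits)
  tibble::tibble(distribution = x$label, out)
}

#' @rdname triangulate
#' @export
triangulate.data.frame <- function(x, include_p_uniform = FALSE, digits = 2, ...) {
  rows <- lapply(seq_len(nrow(x)), function(i) {
    row <- x[i, , drop = FALSE]
    out <- triangulate(collect_estimates(row, include_p_uniform), digits = digits)
    lab <- if ("distribution" %in% names(row)) as.character(row$distribution) else as.character(i)
    tibble::tibble(distribution = lab, out)
  })
  dplyr::bind_rows(rows)
}

#' @rdname triangulate
#' @export
triangulate.numeric <- function(x, digits = 2, ...) {
  if (!"re_mean" %in% names(x)) abort("A named numeric estimate set must contain `re_mean`.")
  triangulate(structure(x, class = "estimate_set"), digits = digits)
}

#' Dollar utility difference between two validity estimates
#'
#' The classic selection-utility difference
#' `dU = n_hired * years * SDy * (validity_a - validity_b) * selectee_z`,
#' where `SDy` is the standard deviation of job performance in dollars
#' (by convention a fraction, default 40%, of salary) and `selectee_z`
#' the average standard score of those hired (default 1.0364, the
#' 85th-percentile score).
#'
#' @param validity_a,validity_b Correlations being compared.
#' @param n_hired Number of employees hired.
#' @param years Expected tenure in years.
#' @param salary Average annual salary in dollars.
#' @param sd_fraction Fraction of salary taken as SDy (default 0.4).
#' @param selectee_z Average selectee standard score (default
#'   `qnorm(0.85)` to four decimals, 1.0364).
#' @return Dollar difference in utility.
#' @examples
#' performance_sd_dollars(44888)
#' utility_difference(.19, .14, 100, 20, 44888)
#' @export
utility_difference <- function(validity_a, validity_b, n_hired, years, salary,
                               sd_fraction = 0.4, selectee_z = 1.0364) {
  if (abs(validity_a) >= 1 || abs(validity_b) >= 1) abort("Validities must be in (-1, 1).")
  if (any(c(n_hired, years, salary, sd_fraction, selectee_z) <= 0)) {
    abort("`n_hired`, `years`, `salary`, `sd_fraction` and `selectee_z` must be positive.")
  }
  n_hired * years * performance_sd_dollars(salary, sd_fraction) *
    (validity_a - validity_b) * selectee_z
}

#' @rdname utility_difference
#' @param fraction Fraction of salary taken as SDy.
#' @export
performance_sd_dollars <- function(salary, fraction = 0.4) {
  if (salary <= 0 || fraction <= 0) abort("`salary` and `fraction` must be positive.")
  fraction * salary
}
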