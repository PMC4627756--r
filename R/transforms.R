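#' Fisher z transformation of a correlation
#'
#' `fisher_z()` maps a Pearson correlation onto the variance-stabilised
#' z scale, `z = arctanh(r)`; `inv_fisher_z()` is its inverse,
#' `r = tanh(z)`. Most pooling and bias procedures in this package operate
#' on the z scale and back-transform their results to correlations.
#'
#' @param r Numeric vector of correlations, each strictly inside (-1, 1).
#' @return Numeric vector of z values.
#' @examples
#' fisher_z(0.5)
#' inv_fisher_z(fisher_z(0.16))
#' @export
fisher_z <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(abs(r) >= 1)) {
    abort("`r` must be numeric with every value strictly between -1 and 1.")
  }
  atanh(r)
}

#' @param z Numeric vector of Fisher z values (finite).
#' @rdname fisher_z
#' @export
inv_fisher_z <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z))) {
    abort("`z` must be a finite numeric vector.")
  }
  tanh(z)
}

#' Sampling variance of a correlation effect size
#'
#' Returns the large-sample sampling variance of a study's effect on the
#' requested analysis scale: `1 / (n - 3)` for Fisher z and
#' `(1 - r^2)^2 / (n - 1)` for the raw correlation.
#'
#' @param r Correlation(s), strictly inside (-1, 1).
#' @param n Sample size(s); must be at least 4 on the z scale so that
#'   `1/(n - 3)` is positive.
#' @param scale `"fisher_z"` or `"raw_r"`.
#' @return Numeric vector of sampling variances.
#' @examples
#' effect_variance(0.2, 103)            # 1/100
#' effect_variance(0, 101, "raw_r")     # 1/100
#' @export
effect_variance <- function(r, n, scale = c("fisher_z", "raw_r")) {
  scale <- match.arg(scale)
  if (any(abs(r) >= 1)) abort("`r` must be strictly between -1 and 1.")
  if (scale == "fisher_z") {
    if (any(n <= 3)) abort("Fisher-z variance 1/(n - 3) requires n >= 4.")
    1 / (n - 3)
  } else {
    if (any(n <= 1)) abort("raw-r variance requires n >= 2.")
    (1 - r^2)^2 / (n - 1)
  }
}

# Effect table on the analysis scale. An `se` column in `data`, when
# present and non-missing, overrides the analytic variance (its square is
# used directly on the requested scale).
effect_table <- function(data, scale = c("fisher_z", "raw_r")) {
  scale <- match.arg(scale)
  check_meta_data(data)
  yi <- if (scale == "fisher_z") atanh(data$r) else data$r
  vi <- effect_variance(data$r, data$n, scale)
  if ("se" %in% names(data)) {
    ov <- !is.na(data$se)
    vi[ov] <- data$se[ov]^2
  }
  tibble::tibble(id = as.character(data$id), yi = yi, vi = vi)
}

back_transform <- function(x, scale) {
  if (scale == "fisher_z") tanh(x) else x
}
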