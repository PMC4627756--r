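#' Contour-enhanced funnel plot data
#'
#' Computes study coordinates and two-sided significance contours for a
#' funnel plot of correlations against precision. Each study is
#' classified by its two-sided p-value into the `significant`
#' (p < .05), `marginal` (.05 <= p < .10) or `nonsignificant` region;
#' the contour boundaries at a given standard error sit at
#' `+/- z_crit * SE`, so asymmetry that tracks the significance
#' boundary, rather than precision alone, points at suppression of
#' nonsignificant results.
#'
#' @param data A study table.
#' @param axis_y Vertical axis: `"inverse_se"` (default, 1/SE),
#'   `"precision"` (1/variance) or `"se"`.
#' @param levels Two-sided significance levels for the contours
#'   (default .05 and .10).
#' @param grid_n Number of SE grid points for the boundary curves.
#' @return An object of class `funnel_contours`: a list with `points`
#'   (tibble: `id`, `effect`, `se`, `y`, `p_two_sided`, `region`),
#'   `boundaries` (tibble: `se`, `y`, `level`, `lower`, `upper`),
#'   `levels`, `axis_y`. Has an [autoplot()] method.
#' @export
funnel_contours <- function(data, axis_y = c("inverse_se", "precision", "se"),
                            levels = c(0.05, 0.10), grid_n = 200) {
  axis_y <- match.arg(axis_y)
  eff <- effect_table(data, "raw_r")
  se <- sqrt(eff$vi)
  y_of <- function(s) switch(axis_y, inverse_se = 1 / s, precision = 1 / s^2, se = s)
  p <- 2 * pnorm(abs(eff$yi) / se, lower.tail = FALSE)
  lv <- sort(levels)
  region <- cut(p, breaks = c(-Inf, lv, Inf),
                labels = c("significant", "marginal", "nonsignificant"))
  se_grid <- seq(min(se) * 0.5, max(se) * 1.1, length.out = grid_n)
  boundaries <- dplyr::bind_rows(lapply(levels, function(l) {
    half <- qnorm(1 - l / 2) * se_grid
    tibble::tibble(se = se_grid, y = y_of(se_grid), level = l,
                   lower = -half, upper = half)
  }))
  structure(list(
    points = tibble::tibble(id = eff$id, effect = eff$yi, se = se,
                            y = y_of(se), p_two_sided = p, region = region),
    boundaries = boundaries,
    levels = levels, axis_y = axis_y
  ), class = "funnel_contours")
}

#' @export
autoplot.funnel_contours <- function(object, ...) {
  b <- object$boundaries
  lv <- sort(object$levels)
  wide <- tidyr::pivot_wider(b, id_cols = c("se", "y"), names_from = "level",
                             values_from = c("lower", "upper"))
  l1 <- paste0("lower_", lv[1]); u1 <- paste0("upper_", lv[1])
  l2 <- paste0("lower_", lv[2]); u2 <- paste0("upper_", lv[2])
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(
      data = wide,
      ggplot2::aes(y = .data$y, xmin = .data[[l2]], xmax = .data[[u2]]),
      fill = "white", orientation = "y") +
    ggplot2::geom_ribbon(
      data = wide,
      ggplot2::aes(y = .data$y, xmin = .data[[l1]], xmax = .data[[l2]]),
      fill = "grey45", orientation = "y") +
    ggplot2::geom_ribbon(
      data = wide,
      ggplot2::aes(y = .data$y, xmin = .data[[u2]], xmax = .data[[u1]]),
      fill = "grey45", orientation = "y") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(
      data = object$points,
      ggplot2::aes(x = .data$effect, y = .data$y), shape = 21, fill = "black") +
    ggplot2::labs(
      x = "Correlation",
      y = switch(object$axis_y, inverse_se = "1 / SE", precision = "1 / variance", se = "SE"),
      title = "Contour-enhanced funnel plot",
      subtitle = "dark band: marginal significance region between the contour levels"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname funnel_contours
#' @param ... Passed to [funnel_contours()].
#' @export
plot_funnel <- function(data, ...) {
  autoplot(funnel_contours(data, ...))
}
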