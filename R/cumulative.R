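#' Cumulative meta-analysis by precision
#'
#' Sorts studies from largest to smallest sample size (ties broken by
#' study id, ascending) and re-pools after each addition under the
#' random-effects model. An upward drift of the cumulative mean as small
#' studies enter is the classic small-study / publication-bias signature;
#' the final step equals the full-dataset pooled result by construction.
#'
#' @param data A study table with at least 2 studies.
#' @param scale Analysis scale (default Fisher z).
#' @param level Confidence level for the step-wise intervals.
#' @return A tibble of class `cumulative_meta` with columns `step`, `id`,
#'   `n`, `k_cum`, `n_cum`, `mean`, `ci_lower`, `ci_upper`. Has an
#'   [autoplot()] method drawing the forest-style drift plot.
#' @export
cumulative_by_precision <- function(data, scale = c("fisher_z", "raw_r"), level = 0.95) {
  scale <- match.arg(scale)
  check_meta_data(data)
  if (nrow(data) < 2) abort("Cumulative meta-analysis requires k >= 2 studies.")
  ord <- order(-as.numeric(data$n), as.character(data$id))
  data <- data[ord, , drop = FALSE]
  eff <- effect_table(data, scale)
  zcrit <- qnorm((1 + level) / 2)
  steps <- lapply(seq_len(nrow(eff)), function(j) {
    fit <- pool_effects(eff$yi[seq_len(j)], eff$vi[seq_len(j)], "random", "DL")
    tibble::tibble(
      step = j, id = eff$id[j], n = as.numeric(data$n[j]),
      k_cum = j, n_cum = sum(as.numeric(data$n[seq_len(j)])),
      mean = back_transform(fit$mu, scale),
      ci_lower = back_transform(fit$mu - zcrit * fit$se, scale),
      ci_upper = back_transform(fit$mu + zcrit * fit$se, scale)
    )
  })
  out <- dplyr::bind_rows(steps)
  class(out) <- c("cumulative_meta", class(out))
  attr(out, "scale") <- scale
  out
}

#' @export
autoplot.cumulative_meta <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean, y = .data$step)) +
    ggplot2::geom_vline(xintercept = object$mean[nrow(object)], linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper),
                            height = 0, colour = "grey40") +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "Cumulative mean correlation (95% CI)",
      y = "Studies entered (largest n first)",
      title = "Cumulative meta-analysis by precision"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname cumulative_by_precision
#' @param ... Passed to [cumulative_by_precision()].
#' @export
plot_cumulative <- function(data, ...) {
  autoplot(cumulative_by_precision(data, ...))
}
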