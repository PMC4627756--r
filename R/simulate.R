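#' Step-function selection (suppression) mechanism
#'
#' Defines the probability that a study is retained (published /
#' retrievable) as a step function of its one-tailed p-value: ascending
#' cut-points ending at 1 and one retention probability per interval,
#' with significant results (the first interval) always retained.
#' Used by [simulate_meta_data()] as the data-generating suppression
#' mechanism; the presets reuse the Vevea-Woods moderate and severe
#' one-tailed weight functions.
#'
#' @param cutpoints Ascending one-tailed p-value breakpoints ending at 1.
#' @param retain_probs Per-interval retention probabilities in (0, 1];
#'   the first must equal 1.
#' @return An object of class `selection_function`.
#' @export
selection_function <- function(cutpoints, retain_probs) {
  if (length(cutpoints) != length(retain_probs)) {
    abort("`cutpoints` and `retain_probs` must have equal length.")
  }
  if (is.unsorted(cutpoints, strictly = TRUE) || tail(cutpoints, 1) != 1 || cutpoints[1] <= 0) {
    abort("`cutpoints` must be strictly ascending within (0, 1] and end at 1.")
  }
  if (retain_probs[1] != 1) abort("The first interval's retention probability must be 1.")
  if (any(retain_probs <= 0) || any(retain_probs > 1)) {
    abort("`retain_probs` must lie in (0, 1].")
  }
  structure(list(cutpoints = cutpoints, retain_probs = retain_probs),
            class = "selection_function")
}

#' @rdname selection_function
#' @export
selection_moderate <- function() {
  selection_function(vevea_woods_steps(), vevea_woods_weights("moderate"))
}

#' @rdname selection_function
#' @export
selection_severe <- function() {
  selection_function(vevea_woods_steps(), vevea_woods_weights("severe"))
}

#' @rdname selection_function
#' @export
selection_none <- function() {
  selection_function(1, 1)
}

#' Retention probability of one-tailed p-values under a selection function
#'
#' @param selection A [selection_function()].
#' @param p One-tailed p-values in (0, 1].
#' @return Numeric vector of retention probabilities.
#' @export
retention_probability <- function(selection, p) {
  if (!inherits(selection, "selection_function")) {
    abort("`selection` must be a selection_function object.")
  }
  selection$retain_probs[p_interval_index(p, selection$cutpoints)]
}

#' @export
print.selection_function <- function(x, ...) {
  cat("One-tailed step-function selection mechanism:\n")
  lo <- c(0, head(x$cutpoints, -1))
  for (j in seq_along(x$cutpoints)) {
    cat(sprintf("  p in (%.3f, %.3f]: retain %.2f\n", lo[j], x$cutpoints[j], x$retain_probs[j]))
  }
  invisible(x)
}

#' Simulate a correlation meta-analysis corpus
#'
#' Generates study-level correlations under the random-effects model the
#' analysis battery assumes, optionally filtered through a one-tailed
#' step-function suppression mechanism. For each candidate study a true
#' effect is drawn as `theta ~ N(mu_z + offset, tau^2)` on the Fisher z
#' scale, a sample size from a floored lognormal, an observed
#' `z ~ N(theta, 1/(n - 3))`, and the study is retained with the
#' probability its one-tailed p-value earns under the selection
#' function. Rejection sampling continues until exactly `k` studies are
#' retained, mirroring a literature in which authors shelve
#' nonsignificant findings.
#'
#' Defaults emulate a large conscientiousness-validity corpus: mean
#' observed correlation near .16 and between-study standard deviation
#' 0.09 on the z scale, with lognormal sample sizes (median about 130).
#'
#' @param k Number of retained studies.
#' @param mu_z True mean effect on the Fisher z scale.
#' @param tau Between-study SD on the z scale.
#' @param n_meanlog,n_sdlog,n_floor Lognormal sample-size model
#'   (floored, rounded).
#' @param selection A [selection_function()] applied to every study, or
#'   `NULL` for no suppression.
#' @param subgroups Optional named list defining moderator subgroups;
#'   each element is `list(fraction =, mu_offset =, selection =)` with
#'   `mu_offset` and `selection` optional. Fractions must sum to 1.
#' @param moderator Column name for the subgroup labels.
#' @param two_tailed Use two-sided p-values in the suppression mechanism
#'   instead of the default one-tailed ones.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param max_draws Abort if more candidate draws than this would be
#'   needed (guards against pathologically low retention).
#' @return A study-table tibble (`id`, `r`, `n`, moderator column when
#'   subgroups are given) with attributes `config`, `n_draws` and
#'   `accept_rate`.
#' @export
simulate_meta_data <- function(k = 113, mu_z = atanh(0.16), tau = 0.081,
                               n_meanlog = log(130), n_sdlog = 0.76, n_floor = 10,
                               selection = NULL, subgroups = NULL,
                               moderator = "subgroup", two_tailed = FALSE,
                               seed = NULL, max_draws = 1e6) {
  if (k < 1) abort("`k` must be at least 1.")
  if (tau < 0) abort("`tau` must be non-negative.")
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_meta_data(
      k = k, mu_z = mu_z, tau = tau, n_meanlog = n_meanlog, n_sdlog = n_sdlog,
      n_floor = n_floor, selection = selection, subgroups = subgroups,
      moderator = moderator, two_tailed = two_tailed, seed = NULL,
      max_draws = max_draws
    )))
  }
  if (!is.null(subgroups)) {
    fr <- vapply(subgroups, function(s) s$fraction, numeric(1))
    if (abs(sum(fr) - 1) > 1e-8) abort("Subgroup fractions must sum to 1.")
    labels <- names(subgroups)
    if (is.null(labels) || any(labels == "")) abort("`subgroups` must be a named list.")
  }
  acc_r <- numeric(0); acc_n <- numeric(0); acc_g <- character(0)
  n_draws <- 0L
  while (length(acc_r) < k) {
    m <- max(2L * k, 64L)
    if (n_draws + m > max_draws) {
      abort(sprintf(
        "Retention too low: more than %g candidate draws needed for k = %d (%d drawn, %d retained).",
        max_draws, k, n_draws, length(acc_r)))
    }
    n_draws <- n_draws + m
    if (is.null(subgroups)) {
      g <- rep(NA_character_, m)
      offs <- rep(0, m)
      sel_of <- function(gi) selection
    } else {
      g <- sample(names(subgroups), m, replace = TRUE,
                  prob = vapply(subgroups, function(s) s$fraction, numeric(1)))
      offs <- vapply(g, function(gi) subgroups[[gi]]$mu_offset %||% 0, numeric(1))
      sel_of <- function(gi) subgroups[[gi]]$selection %||% selection
    }
    n <- pmax(n_floor, round(rlnorm(m, n_meanlog, n_sdlog)))
    n <- pmax(n, 4)
    theta <- rnorm(m, mu_z + offs, tau)
    v <- 1 / (n - 3)
    z <- rnorm(m, theta, sqrt(v))
    p <- if (two_tailed) {
      2 * pnorm(abs(z) / sqrt(v), lower.tail = FALSE)
    } else {
      pnorm(z / sqrt(v), lower.tail = FALSE)
    }
    prob <- rep(1, m)
    for (gi in unique(g)) {
      sel <- sel_of(gi)
      if (!is.null(sel)) {
        rows <- if (is.na(gi)) seq_len(m) else which(g == gi)
        prob[rows] <- retention_probability(sel, p[rows])
      }
    }
    keep <- runif(m) < prob
    acc_r <- c(acc_r, tanh(z[keep]))
    acc_n <- c(acc_n, n[keep])
    acc_g <- c(acc_g, g[keep])
  }
  idx <- seq_len(k)
  out <- tibble::tibble(
    id = sprintf("S%04d", idx),
    r = acc_r[idx],
    n = as.numeric(acc_n[idx])
  )
  if (!is.null(subgroups)) out[[moderator]] <- acc_g[idx]
  attr(out, "config") <- list(
    k = k, mu_z = mu_z, tau = tau, n_meanlog = n_meanlog, n_sdlog = n_sdlog,
    n_floor = n_floor, two_tailed = two_tailed,
    subgroups = if (is.null(subgroups)) NULL else names(subgroups)
  )
  attr(out, "n_draws") <- n_draws
  attr(out, "accept_rate") <- k / n_draws
  out
}

# True z-scale mean of the preset validity corpus, calibrated once (by
# simulation over many corpora) so that the suppressed corpus's expected
# random-effects mean correlation is about .16.
corpus_mu_z <- function() 0.122

#' Preset validity-generalisation corpus
#'
#' Generates a 113-study correlation corpus shaped like a large
#' conscientiousness-job performance validity literature: between-study
#' SD 0.09 on the z scale, lognormal sample sizes (median about 130,
#' floor 30, expected total N near 19,600), a 60/40 split between a
#' `journal` subgroup under severe one-tailed suppression and a
#' `non_journal` subgroup under moderate suppression, and the true mean
#' calibrated so the suppressed corpus pools to a mean observed
#' correlation of about .16. A `frame_of_reference` moderator
#' (non-contextualized / contextualized, about 80/20) is attached
#' independently so moderator crossings can be exercised.
#'
#' @param seed Optional integer seed.
#' @return A study-table tibble with moderators `source` and
#'   `frame_of_reference`.
#' @export
simulate_validity_corpus <- function(seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_validity_corpus(seed = NULL)))
  }
  out <- simulate_meta_data(
    k = 113, mu_z = corpus_mu_z(), tau = 0.09,
    n_meanlog = log(130), n_sdlog = 0.76, n_floor = 30,
    subgroups = list(
      journal = list(fraction = 0.6, selection = selection_severe()),
      non_journal = list(fraction = 0.4, selection = selection_moderate())
    ),
    moderator = "source"
  )
  out$frame_of_reference <- ifelse(runif(nrow(out)) < 0.2,
                                   "contextualized", "non_contextualized")
  out
}
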