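# Small in-code fixtures and independent oracles used across the suite.

toy_studies <- function(r, n, id = sprintf("s%02d", seq_along(r)), ...) {
  tibble::tibble(id = id, r = r, n = n, ...)
}

homogeneous_studies <- function(k, r = 0.3, n = 100) {
  toy_studies(rep(r, k), rep(n, k))
}

# Study table from z-scale effects with known variances, via the se
# override column (se on the fisher_z scale equals sqrt(v)).
studies_from_z <- function(z, v, n = 100) {
  tibble::tibble(id = sprintf("z%02d", seq_along(z)), r = tanh(z), n = n,
                 se = sqrt(v))
}

# Independent iterative L0 trim-and-fill oracle (rank-based estimator,
# fixed-effect centring while trimming, left-side suppression assumed):
# returns k0 and the mirror-imputed effects.
oracle_trimfill_left <- function(y, v, max_iter = 50) {
  k <- length(y)
  k0 <- 0
  for (iter in seq_len(max_iter)) {
    keep <- seq_len(k - k0)            # drop the k0 largest values
    ord <- order(y)
    trimmed <- ord[keep]
    w <- 1 / v[trimmed]
    centre <- sum(w * y[trimmed]) / sum(w)
    d <- y - centre
    rk <- rank(abs(d))
    Tn <- sum(rk[d > 0])
    L0 <- (4 * Tn - k * (k + 1)) / (2 * k - 1)
    k0_new <- max(0L, as.integer(round(L0)))
    if (k0_new == k0) break
    k0 <- k0_new
  }
  if (k0 == 0) return(list(k0 = 0L, y_imp = numeric(0), v_imp = numeric(0), centre = centre))
  ord <- order(y)
  top <- rev(ord)[seq_len(k0)]
  list(k0 = as.integer(k0), y_imp = 2 * centre - y[top], v_imp = v[top], centre = centre)
}

# Independent DerSimonian-Laird oracle on (y, v).
oracle_dl <- function(y, v) {
  k <- length(y)
  w <- 1 / v
  mu_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_fe)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (v + tau2)
  list(mu = sum(wr * y) / sum(wr), se = sqrt(1 / sum(wr)), Q = Q, tau2 = tau2)
}
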