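# R-side assembly of the stacked-site dynamic linear model and the FFBS
# draw of the latent factor path.  State ordering is factor-major:
# component (m - 1) * n + i is factor m at site i; observation cells are
# pollutant-major: (p - 1) * n + i.

# T x (n P) observation matrix from the panel array
panel_obs_matrix <- function(panel) {
  d <- panel_dims(panel)
  matrix(panel$Y, nrow = d$T, ncol = d$n * d$P)
}

# r x d observation matrix H: H[(p-1)n + i, (m-1)n + i] = lambda[i, p, m]
loading_obs_matrix <- function(lambda) {
  n <- dim(lambda)[1]; P <- dim(lambda)[2]; M <- dim(lambda)[3]
  H <- matrix(0, n * P, n * M)
  for (p in seq_len(P)) for (m in seq_len(M)) {
    idx <- cbind((p - 1L) * n + seq_len(n), (m - 1L) * n + seq_len(n))
    H[idx] <- lambda[, p, m]
  }
  H
}

# T x (nP) matrix of observation means
observation_mean_matrix <- function(panel, ms) {
  d <- panel_dims(panel)
  mu <- mean_matrix(ms, panel$network)                 # n x P
  base <- matrix(rep(as.numeric(mu), each = d$T), nrow = d$T)
  harm <- harmonic_matrix(ms, d$T)                     # T x P or NULL
  if (!is.null(harm))
    base <- base + harm[, rep(seq_len(d$P), each = d$n), drop = FALSE]
  base
}

# covariance of the stacked innovation/initial state from per-factor hypers
stacked_state_cov <- function(corr, variances) {
  M <- length(variances)
  n <- nrow(corr[[1]])
  W <- matrix(0, n * M, n * M)
  for (m in seq_len(M)) {
    idx <- (m - 1L) * n + seq_len(n)
    W[idx, idx] <- variances[m] * corr[[m]]
  }
  W
}

#' Draw the latent factor path by forward filtering, backward sampling
#'
#' Exact draw of `delta_{0:T}` from its full conditional given the panel
#' and the current parameters, on the stacked `n * M`-dimensional state
#' (innovations are spatially correlated across sites).  Missing cells are
#' skipped in the measurement update.
#'
#' @param panel a [pollutant_panel()].
#' @param ms,ev mean structure and error variances.
#' @param lambda `n x P x M` loading array.
#' @param gamma `n x M` propagation coefficients in (-1, 1).
#' @param innovation_hyper [gp_hyper()] for the innovation process `w_t`
#'   (shared across factors).
#' @param delta0_hyper list of M [gp_hyper()] objects for the initial state.
#' @param sample draw a path (default) and/or
#' @param moments return smoother means and marginal covariances.
#' @param kernel correlation kernel.
#' @return list with `delta0` (`n x M`), `delta` (`T x n x M`), `loglik`,
#'   and when `moments = TRUE` also `smooth_mean` (`(T+1) x nM`) and
#'   `smooth_cov` (`nM x nM x (T+1)`).
#' @export
ffbs_factors <- function(panel, ms, ev, lambda, gamma, innovation_hyper,
                         delta0_hyper, sample = TRUE, moments = FALSE,
                         kernel = "exponential") {
  d <- panel_dims(panel)
  M <- dim(lambda)[3]
  corr_w <- correlation_matrix(panel$sites, innovation_hyper$range, kernel)
  W <- stacked_state_cov(rep(list(corr_w), M),
                         rep(innovation_hyper$variance, M))
  C0 <- stacked_state_cov(
    lapply(delta0_hyper, function(h)
      correlation_matrix(panel$sites, h$range, kernel)),
    vapply(delta0_hyper, `[[`, numeric(1), "variance"))
  res <- .ffbs_cpp(panel_obs_matrix(panel), loading_obs_matrix(lambda),
                   observation_mean_matrix(panel, ms),
                   as.numeric(variance_matrix(ev, panel$network)),
                   as.numeric(gamma), W, rep(0, d$n * M), C0,
                   sample, moments)
  out <- list(loglik = res$loglik)
  if (sample) {
    x <- res$draw
    out$delta0 <- matrix(x[1, ], d$n, M)
    out$delta <- array(x[-1, , drop = FALSE], dim = c(d$T, d$n, M))
  }
  if (moments) {
    out$smooth_mean <- res$smooth_mean
    out$smooth_cov <- res$smooth_cov
  }
  out
}
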