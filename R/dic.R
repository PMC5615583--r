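# Model comparison over the number of latent factors by DIC, computed on
# the health-outcome likelihood (the bivariate probit), and posterior
# predictive classification of observed defects.

#' Deviance of the bivariate outcome likelihood at one draw
#'
#' `-2 sum_i log P(Y~_i | eta_i, Omega)` with the joint (rectangle)
#' bivariate-probit likelihood; additive over subjects.  The quadrant
#' probability depends only on `eta / sqrt(diag(Omega))` and the latent
#' correlation, so the deviance is invariant to the probit scale
#' indeterminacy.
#'
#' @param y `N x 2` outcomes.
#' @param eta `N x 2` latent means.
#' @param omega 2 x 2 latent covariance.
#' @return scalar deviance.
#' @export
deviance_bivariate <- function(y, eta, omega) {
  -2 * sum(outcome_logprob_matrix(eta, omega, y))
}

#' Deviance information criterion from draw-wise deviances
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(theta_bar)`; both identities hold
#' exactly by construction.  Lower is better.
#'
#' @param deviances vector of draw-wise deviances (length >= 2).
#' @param d_at_mean deviance evaluated at the posterior mean of the
#'   parameters.
#' @return object of class `dic_result` with fields `dbar`, `d_at_mean`,
#'   `pD`, `dic`.
#' @export
dic <- function(deviances, d_at_mean) {
  if (length(deviances) < 2L) stop("need at least two draws")
  dbar <- mean(deviances)
  pd <- dbar - d_at_mean
  structure(list(dbar = dbar, d_at_mean = d_at_mean, pD = pd,
                 dic = dbar + pd),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC %.2f  (Dbar %.2f, pD %.2f)\n", x$dic, x$dbar, x$pD))
  invisible(x)
}

#' DIC of a fitted joint model
#'
#' Draw-wise deviances use each stored draw's `(beta, w, Omega, exposures)`;
#' the plug-in deviance uses posterior means of `beta`, `w` and the
#' exposures on the unit-variance reporting scale with the posterior mean
#' latent correlation (the covariance is averaged on the correlation scale
#' to avoid scale drift).  By default only the health-outcome likelihood
#' enters; `include_pollutant = TRUE` adds the pollutant-panel likelihood
#' for a total-model DIC.
#'
#' @param fit a [run_gibbs()] result with health draws.
#' @param cohort the fitted [cohort_table()].
#' @param panel the fitted [pollutant_panel()] (needed only when
#'   `include_pollutant = TRUE`).
#' @param include_pollutant add the pollutant likelihood.
#' @return a [dic()] result.
#' @export
dic_fit <- function(fit, cohort, panel = NULL, include_pollutant = FALSE) {
  dr <- fit$draws
  if (is.null(dr$beta)) stop("fit has no health-model draws")
  n <- fit$N; q <- length(fit$covariate_names); M <- fit$M
  S <- nrow(dr$beta)
  devs <- numeric(S)
  beta_std <- matrix(0, q, 2); w_std <- matrix(0, 6 * M, 2)
  d_std <- matrix(0, n, 6 * M); rho_bar <- 0
  for (s in seq_len(S)) {
    beta <- matrix(dr$beta[s, ], q, 2)
    wmat <- matrix(dr$w[s, ], 6 * M, 2)
    omega <- matrix(dr$omega[s, ], 2, 2)
    D <- matrix(dr$exposure[s, ], n, 6 * M)
    eta <- latent_mean_matrix(beta, wmat, cohort$x, D)
    devs[s] <- deviance_bivariate(cohort$y, eta, omega)
    sc <- sqrt(diag(omega))
    beta_std <- beta_std + sweep(beta, 2, sc, "/")
    w_std <- w_std + sweep(wmat, 2, sc, "/")
    d_std <- d_std + D
    rho_bar <- rho_bar + omega[1, 2] / prod(sc)
  }
  beta_std <- beta_std / S; w_std <- w_std / S
  d_std <- d_std / S; rho_bar <- rho_bar / S
  omega_bar <- matrix(c(1, rho_bar, rho_bar, 1), 2, 2)
  eta_bar <- latent_mean_matrix(beta_std, w_std, cohort$x, d_std)
  d_at_mean <- deviance_bivariate(cohort$y, eta_bar, omega_bar)
  if (include_pollutant) {
    if (is.null(panel)) stop("panel needed for the pollutant likelihood")
    devs <- devs + pollutant_deviances(fit, panel)
    d_at_mean <- d_at_mean + attr(devs, "at_mean")
  }
  dic(as.numeric(devs), d_at_mean)
}

# draw-wise pollutant deviances (optional total-model DIC); plug-in value
# returned as an attribute
pollutant_deviances <- function(fit, panel) {
  dr <- fit$draws
  if (is.null(dr$delta)) stop("fit did not store the factor path")
  d <- fit$dims; M <- fit$M
  S <- nrow(dr$mu0)
  devs <- numeric(S)
  acc <- list()
  for (s in seq_len(S)) {
    ms <- mean_structure(dr$mu0[s, ], dr$mu1[s, ])
    ev <- error_variances(dr$sigma2_stn[s, ], dr$sigma2_imp[s, ])
    lf_free <- relist_free(dr$free_loadings[s, ], d$n, d$P, M)
    lambda <- constrain_loadings(matrix(dr$log_diag[s, ], d$n, M), lf_free,
                                 d$P, M)
    delta <- array(dr$delta[s, ], dim = c(d$T, d$n, M))
    devs[s] <- -2 * pollutant_loglik(panel, ms, ev, lambda, delta)
    acc$mu0 <- c(acc$mu0, list(dr$mu0[s, ]))
  }
  # plug-in at posterior means of all blocks
  ms <- mean_structure(colMeans(dr$mu0), colMeans(dr$mu1))
  ev <- error_variances(colMeans(dr$sigma2_stn), colMeans(dr$sigma2_imp))
  lambda <- constrain_loadings(matrix(colMeans(dr$log_diag), d$n, M),
                               relist_free(colMeans(dr$free_loadings),
                                           d$n, d$P, M), d$P, M)
  delta <- array(colMeans(dr$delta), dim = c(d$T, d$n, M))
  out <- devs
  attr(out, "at_mean") <- -2 * pollutant_loglik(panel, ms, ev, lambda, delta)
  out
}

relist_free <- function(v, n, P, M) {
  keys <- free_loading_keys(P, M)
  if (!length(keys)) return(list())
  m <- matrix(v, n, length(keys))
  stats::setNames(lapply(seq_along(keys), function(j) m[, j]), keys)
}

#' Posterior-predictive classification sensitivity
#'
#' Fraction of observed defects (pooled over cleft palate and cleft lip)
#' whose posterior predictive defect probability exceeds the threshold:
#' `P(Yhat = 1 | Y = 1)`.
#'
#' @param cohort the fitted [cohort_table()].
#' @param fit a [run_gibbs()] result.
#' @param threshold classification threshold (default 0.5).
#' @return scalar sensitivity in [0, 1].
#' @export
classification_sensitivity <- function(cohort, fit, threshold = 0.5) {
  probs <- predictive_probs(fit, cohort)
  cases <- cohort$y == 1
  if (!any(cases)) stop("no observed defects: sensitivity undefined")
  mean(probs[cases] > threshold)
}
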