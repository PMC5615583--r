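# Full-conditional updates for the Gibbs sampler.  Conjugate where the
# model admits it (inverse-gamma variances, normal means and offsets,
# Gaussian site-blocks for free loadings, inverse-Wishart outcome
# covariance), elliptical slice sampling for the log-diagonal loading
# fields, coordinate-wise truncated-normal Gibbs for the propagation
# field, and discrete-grid Gibbs for GP range parameters.

# ---- error variances -------------------------------------------------------

#' Conjugate update of the network/pollutant error variances
#'
#' Inverse-gamma full conditional `IG(a + k/2, b + SS/2)` per
#' (network, pollutant) cell group, where `k` and `SS` are the count and
#' sum of squares of the non-missing residuals.  An empty group draws from
#' the prior.
#'
#' @param panel a [pollutant_panel()].
#' @param fit fitted mean array from the current draw (`T x n x P`).
#' @param prior `c(a, b)` inverse-gamma prior (shape, rate).
#' @return an [error_variances()] draw.
#' @export
update_error_variances <- function(panel, fit, prior = c(2, 1)) {
  d <- panel_dims(panel)
  resid <- panel$Y - fit
  is_stn <- panel$network == "STN"
  draw_one <- function(r) {
    k <- sum(is.finite(r))
    ss <- sum(r[is.finite(r)]^2)
    1 / stats::rgamma(1, shape = prior[1] + k / 2, rate = prior[2] + ss / 2)
  }
  s2_stn <- vapply(seq_len(d$P), function(p)
    draw_one(resid[, is_stn, p, drop = FALSE]), numeric(1))
  s2_imp <- vapply(seq_len(d$P), function(p)
    draw_one(resid[, !is_stn, p, drop = FALSE]), numeric(1))
  error_variances(s2_stn, s2_imp)
}

# ---- mean structure --------------------------------------------------------

#' Conjugate update of the network mean offsets
#'
#' Normal-normal Gibbs draws of the IMPROVE-level intercepts `mu0[p]` (from
#' all cells) and the STN offsets `mu1[p]` (from STN cells only), under
#' independent `N(0, prior_var)` priors.  When the mean structure carries
#' annual harmonics their amplitudes are updated the same way.
#'
#' @param panel a [pollutant_panel()].
#' @param ms current [mean_structure()].
#' @param ev current [error_variances()].
#' @param factor_fit `T x n x P` array `Lambda(s) delta_t(s)` (fitted means
#'   excluding the mean structure).
#' @param prior_var prior variance (default 100).
#' @return a [mean_structure()] draw.
#' @export
update_mean_offsets <- function(panel, ms, ev, factor_fit, prior_var = 100) {
  d <- panel_dims(panel)
  r <- panel$Y - factor_fit
  vmat <- variance_matrix(ev, panel$network)        # n x P
  is_stn <- panel$network == "STN"
  mu0 <- ms$mu0; mu1 <- ms$mu1
  amp_cos <- ms$amp_cos; amp_sin <- ms$amp_sin
  tt <- 2 * pi * seq_len(d$T) / ms$period
  for (p in seq_len(d$P)) {
    rp <- r[, , p]                                  # T x n
    wp <- matrix(1 / vmat[, p], d$T, d$n, byrow = TRUE)
    wp[!is.finite(rp)] <- 0
    rp[!is.finite(rp)] <- 0
    harm <- if (!is.null(amp_cos))
      outer(cos(tt), rep(1, d$n)) * amp_cos[p] +
      outer(sin(tt), rep(1, d$n)) * amp_sin[p] else 0
    stn_mat <- matrix(as.numeric(is_stn), d$T, d$n, byrow = TRUE)
    draw_coef <- function(reg, part_resid) {
      prec <- 1 / prior_var + sum(wp * reg^2)
      mean <- sum(wp * reg * part_resid) / prec
      stats::rnorm(1, mean, sqrt(1 / prec))
    }
    mu0[p] <- draw_coef(matrix(1, d$T, d$n),
                        rp - mu1[p] * stn_mat - harm)
    mu1[p] <- draw_coef(stn_mat, rp - mu0[p] - harm)
    if (!is.null(amp_cos)) {
      base <- rp - mu0[p] - mu1[p] * stn_mat
      cosm <- outer(cos(tt), rep(1, d$n))
      sinm <- outer(sin(tt), rep(1, d$n))
      amp_cos[p] <- draw_coef(cosm, base - amp_sin[p] * sinm)
      amp_sin[p] <- draw_coef(sinm, base - amp_cos[p] * cosm)
    }
  }
  mean_structure(mu0, mu1, amp_cos, amp_sin, ms$period)
}

# ---- loadings --------------------------------------------------------------

# elliptical slice sampling step: prior N(0, Sigma) via its upper Cholesky,
# generic log-likelihood
ess_step <- function(g, prior_chol, loglik_fn) {
  nu <- drop(crossprod(prior_chol, stats::rnorm(length(g))))
  logy <- loglik_fn(g) + log(stats::runif(1))
  theta <- stats::runif(1, 0, 2 * pi)
  lo <- theta - 2 * pi; hi <- theta
  repeat {
    gp <- g * cos(theta) + nu * sin(theta)
    if (loglik_fn(gp) >= logy) return(gp)
    if (theta < 0) lo <- theta else hi <- theta
    theta <- stats::runif(1, lo, hi)
    if (hi - lo < 1e-12) return(g)
  }
}

#' Update the spatial loading fields
#'
#' Free (sub-diagonal) entries get exact site-block Gaussian full
#' conditionals under their GP priors; the log-diagonal fields are updated
#' by elliptical slice sampling (the exp link breaks conjugacy), which has
#' no tuning parameters.  Structural zeros are preserved exactly.
#'
#' @param panel a [pollutant_panel()].
#' @param ms,ev current mean structure and error variances.
#' @param lf loading field state: list with `log_diag` (`n x M`), `free`
#'   (named list of n-vectors), `P`, `M`.
#' @param delta `T x n x M` current factor path.
#' @param hypers list with per-entry GP hypers: `s2` and `chol` (upper
#'   Cholesky of the unit correlation at the entry's range) keyed like the
#'   free entries plus `"d.p"` for diagonals.
#' @param ess_reps elliptical-slice steps per diagonal field per call
#'   (more steps cost little and improve mixing along the loading/factor
#'   scale ridge).
#' @return updated `lf`.
#' @export
update_loadings <- function(panel, ms, ev, lf, delta, hypers, ess_reps = 3L) {
  d <- panel_dims(panel)
  M <- lf$M
  lambda <- constrain_loadings(lf$log_diag, lf$free, lf$P, M)
  fit <- fitted_mean_array(panel, ms, lambda, delta)
  vmat <- variance_matrix(ev, panel$network)
  # free entries: site-block Gaussian
  for (key in free_loading_keys(lf$P, M)) {
    pf <- as.integer(strsplit(key, ".", fixed = TRUE)[[1]])
    p <- pf[1]; f <- pf[2]
    cur <- lf$free[[key]]
    if (is.null(cur)) cur <- rep(0, d$n)
    del <- matrix(delta[, , f], d$T, d$n)           # T x n
    rp <- matrix(panel$Y[, , p], d$T, d$n) - matrix(fit[, , p], d$T, d$n) +
      sweep(del, 2, cur, "*")
    obs <- is.finite(rp)
    rp[!obs] <- 0; delobs <- del; delobs[!obs] <- 0
    dvec <- colSums(delobs^2) / vmat[, p]
    bvec <- colSums(delobs * rp) / vmat[, p]
    h <- hypers[[key]]
    kinv <- chol2inv(h$chol) / h$s2
    A <- kinv + diag(dvec, d$n)
    u <- chol_jitter(A)
    mean_vec <- backsolve(u, forwardsolve(t(u), bvec))
    new <- mean_vec + backsolve(u, stats::rnorm(d$n))
    lf$free[[key]] <- new
    fit[, , p] <- fit[, , p] + sweep(del, 2, new - cur, "*")
  }
  # diagonal entries: elliptical slice sampling on the log field
  for (p in seq_len(M)) {
    cur <- lf$log_diag[, p]
    del <- matrix(delta[, , p], d$T, d$n)           # T x n (factor f = p)
    base <- matrix(fit[, , p], d$T, d$n) - sweep(del, 2, exp(cur), "*")
    yobs <- matrix(panel$Y[, , p], d$T, d$n)
    obs <- is.finite(yobs)
    sdm <- matrix(sqrt(vmat[, p]), d$T, d$n, byrow = TRUE)
    h <- hypers[[paste0("d.", p)]]
    llfun <- function(g) {
      mu <- base + sweep(del, 2, exp(g), "*")
      sum(stats::dnorm(yobs[obs], mu[obs], sdm[obs], log = TRUE))
    }
    new <- cur
    for (r in seq_len(ess_reps)) new <- ess_step(new, sqrt(h$s2) * h$chol,
                                                 llfun)
    lf$log_diag[, p] <- new
    fit[, , p] <- base + sweep(del, 2, exp(new), "*")
  }
  lf
}

# ---- propagation field -----------------------------------------------------

#' Update the factor propagation field gamma
#'
#' Per factor, the full conditional of the site vector `gamma_f` combines
#' the AR likelihood of the factor path (with spatially correlated
#' innovations) and the box-truncated GP prior; optional extra Gaussian
#' terms (exposure-site couplings) enter the same quadratic form.  Sampling
#' is coordinate-wise Gibbs over univariate truncated normals on (-1, 1);
#' when non-Gaussian correction terms are supplied (truncation normalising
#' constants of mother-site conditionals) each coordinate move becomes a
#' Metropolis step with the Gibbs draw as proposal.
#'
#' @param delta0 `n x M`; `delta` `T x n x M` current path.
#' @param gamma current `n x M` field.
#' @param prior_kinv list of M precision matrices of the (untruncated)
#'   Gaussian kernel of the truncated-GP prior.
#' @param q_innov precision matrix of the innovation field
#'   (`R_w^{-1} / s_w^2`).
#' @param extra optional list of M lists with fields `A`, `b` (additional
#'   Gaussian precision/linear terms) and `logcorr(gam)` (log of the
#'   non-Gaussian correction for the factor's site vector).
#' @param sweeps Gibbs sweeps (default 10).
#' @return updated `n x M` gamma with all entries in (-1, 1).
#' @export
update_propagation <- function(delta0, delta, gamma, prior_kinv, q_innov,
                               extra = NULL, sweeps = 10L) {
  n <- nrow(gamma); M <- ncol(gamma)
  tt <- dim(delta)[1]
  for (f in seq_len(M)) {
    dprev <- t(rbind(delta0[, f], matrix(delta[, , f], tt, n)[-tt, ,
                                                              drop = FALSE]))
    dcur <- t(matrix(delta[, , f], tt, n))          # n x T
    S <- tcrossprod(dprev)
    A <- prior_kinv[[f]] + q_innov * S
    b <- rowSums(dprev * (q_innov %*% dcur))
    logcorr <- NULL
    if (!is.null(extra) && !is.null(extra[[f]])) {
      A <- A + extra[[f]]$A
      b <- b + extra[[f]]$b
      logcorr <- extra[[f]]$logcorr
    }
    gam <- gamma[, f]
    csd <- sqrt(1 / diag(A))
    for (s in seq_len(sweeps)) {
      for (i in seq_len(n)) {
        m_i <- (b[i] - (sum(A[i, ] * gam) - A[i, i] * gam[i])) / A[i, i]
        prop <- rtnorm1(m_i, csd[i], -1, 1)
        if (is.null(logcorr)) {
          gam[i] <- prop
        } else {
          old <- gam[i]
          gam[i] <- prop
          lr <- logcorr(gam)
          gam[i] <- old
          lr <- lr - logcorr(gam)
          if (log(stats::runif(1)) < lr) gam[i] <- prop
        }
      }
    }
    gamma[, f] <- gam
  }
  gamma
}

# ---- probit block ----------------------------------------------------------

#' Gibbs update of the latent probit utilities
#'
#' For each subject, alternate draws of the two coordinates of
#' `Z_i ~ N(eta_i, Omega)` from univariate truncated normals respecting the
#' observed outcomes (`z_ij > 0` iff `y_ij = 1`), conditioning on the other
#' coordinate through `Omega`.  Vectorised over subjects.
#'
#' @param y `N x 2` outcomes; `eta` `N x 2` latent means; `omega` 2 x 2
#'   SPD; `z` current `N x 2` utilities.
#' @return updated `N x 2` matrix.
#' @export
update_probit_latents <- function(y, eta, omega, z) {
  n <- nrow(y)
  for (j in 1:2) {
    k <- 3 - j
    slope <- omega[j, k] / omega[k, k]
    csd <- sqrt(omega[j, j] - omega[j, k]^2 / omega[k, k])
    m <- eta[, j] + slope * (z[, k] - eta[, k])
    z[, j] <- rtnorm(n, m, csd,
                     lower = ifelse(y[, j] == 1, 0, -Inf),
                     upper = ifelse(y[, j] == 1, Inf, 0))
  }
  z
}

#' Joint Gaussian update of covariate and weekly-exposure coefficients
#'
#' Stacks `(beta, w)` for both defects and draws the exact multivariate
#' normal full conditional given the latent utilities, under the `N(0, I)`
#' prior on `beta` and the weekly GP prior on `w` (standard Bayesian
#' linear-model algebra on the latent Gaussian regression
#' `Z = [X D] B + E`, `E ~ N(0, Omega)` rowwise).
#'
#' @param X `N x q` covariates; `D` `N x 6M` exposure design; `z` `N x 2`
#'   latent utilities; `omega` 2 x 2 covariance.
#' @param w_kinv `6M x 6M` precision of the weekly GP prior.
#' @return list with `beta` (`q x 2`) and `wmat` (`6M x 2`).
#' @export
update_beta_weekly <- function(X, D, z, omega, w_kinv) {
  q <- ncol(X); r <- ncol(D); k <- q + r
  Xf <- cbind(X, D)
  if (nrow(Xf) > 0 && qr(Xf)$rank < k)
    warning("rank-deficient design; prior regularizes the update")
  oinv <- solve(omega)
  xtx <- crossprod(Xf)
  p0 <- matrix(0, k, k)
  p0[seq_len(q), seq_len(q)] <- diag(q)
  if (r > 0) p0[q + seq_len(r), q + seq_len(r)] <- w_kinv
  A <- kronecker(oinv, xtx) + kronecker(diag(2), p0)
  rhs <- as.numeric(crossprod(Xf, z %*% oinv))
  u <- chol_jitter(A)
  mean_vec <- backsolve(u, forwardsolve(t(u), rhs))
  bvec <- mean_vec + backsolve(u, stats::rnorm(2 * k))
  B <- matrix(bvec, k, 2)
  list(beta = B[seq_len(q), , drop = FALSE],
       wmat = B[q + seq_len(r), , drop = FALSE])
}

#' Conjugate inverse-Wishart update of the outcome covariance
#'
#' `Omega | . ~ IW(Psi + sum_i e_i e_i', nu + N)` with prior `IW(I2, 2)`
#' and residuals `e_i = z_i - eta_i`.  Used as the expanded-scale draw
#' inside the parameter-expanded correlation update and directly in
#' prior-simulation contexts.
#'
#' @param resid `N x 2` latent residuals (possibly 0 rows).
#' @param prior_scale,prior_df prior scale matrix and degrees of freedom.
#' @return a 2 x 2 SPD draw.
#' @export
update_omega <- function(resid, prior_scale = diag(2), prior_df = 2) {
  psi <- prior_scale + if (nrow(resid)) crossprod(resid) else 0
  df <- prior_df + nrow(resid)
  winv <- stats::rWishart(1, df, solve(psi))[, , 1]
  omega <- solve(winv)
  (omega + t(omega)) / 2
}

#' Exact grid update of the outcome correlation
#'
#' The latent utilities live on the identified unit-variance scale
#' (`Z ~ N(eta, R)` with `R` a correlation matrix, so defect
#' probabilities are exactly `Phi` of the linear predictor).  The
#' correlation takes a uniform prior over a fine symmetric grid on
#' (-1, 1) and is drawn from its exact discrete full conditional, which
#' depends on the residuals only through the sufficient statistics
#' `sum e1^2`, `sum e2^2`, `sum e1 e2`.
#'
#' @param resid `N x 2` identified-scale residuals `z - eta`.
#' @param grid correlation grid (default 397 points on +-0.99).
#' @return sampled correlation, with the normalized grid weights as
#'   attribute `"weights"`.
#' @export
update_rho_grid <- function(resid, grid = seq(-0.99, 0.99, by = 0.005)) {
  n <- nrow(resid)
  if (n == 0L) return(sample(grid, 1L))
  s11 <- sum(resid[, 1]^2); s22 <- sum(resid[, 2]^2)
  s12 <- sum(resid[, 1] * resid[, 2])
  lw <- -(n / 2) * log(1 - grid^2) -
    (s11 + s22 - 2 * grid * s12) / (2 * (1 - grid^2))
  lw <- lw - max(lw)
  wts <- exp(lw) / sum(exp(lw))
  out <- grid[sample.int(length(grid), 1L, prob = wts)]
  attr(out, "weights") <- wts
  out
}

# ---- GP hyperparameters ----------------------------------------------------

# quadratic form x' R^{-1} x via the unit-correlation Cholesky
corr_quad <- function(chol_u, x) {
  z <- forwardsolve(t(chol_u), x)
  if (is.matrix(z)) colSums(z^2) else sum(z^2)
}

#' Conjugate inverse-gamma variance update for a GP field
#'
#' `s2 | field ~ IG(a + k/2, b + Q/2)` where `Q` sums unit-correlation
#' quadratic forms (plus any exposure-site contributions with their
#' conditional-variance scales) and `k` counts the field values.
#'
#' @param quad total quadratic form on the unit-variance scale.
#' @param count number of field values behind `quad`.
#' @param prior `c(a, b)` shape and rate.
#' @export
update_gp_variance <- function(quad, count, prior = c(2, 1)) {
  1 / stats::rgamma(1, shape = prior[1] + count / 2,
                    rate = prior[2] + quad / 2)
}

#' Discrete-grid Gibbs update of a GP range parameter
#'
#' Evaluates the Gaussian log density of the field(s) at each candidate
#' range (Cholesky factors precomputed per grid point), adds any extra
#' terms, and samples the grid index from the normalized weights.
#'
#' @param fields matrix (n x k) whose columns are field realisations
#'   sharing the candidate range.
#' @param s2 marginal variance of the field(s).
#' @param chol_list list of upper Cholesky factors of the unit correlation,
#'   one per grid value.
#' @param extra optional function(grid index) returning an additional log
#'   weight (exposure-site terms in feedback mode).
#' @return sampled grid index, with attribute `"weights"`.
#' @export
update_gp_range <- function(fields, s2, chol_list, extra = NULL) {
  fields <- as.matrix(fields)
  k <- ncol(fields)
  lw <- vapply(seq_along(chol_list), function(g) {
    u <- chol_list[[g]]
    -k * sum(log(diag(u))) - sum(corr_quad(u, fields)) / (2 * s2) +
      (if (is.null(extra)) 0 else extra(g))
  }, numeric(1))
  lw <- lw - max(lw)
  wts <- exp(lw) / sum(exp(lw))
  idx <- sample.int(length(wts), 1L, prob = wts)
  attr(idx, "weights") <- wts
  idx
}
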