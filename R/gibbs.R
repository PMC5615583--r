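# The joint Gibbs sampler: the pollutant factor model and the birth-defect
# probit model are fit in one algorithm.  Each sweep runs FFBS for the
# latent factor path, conjugate updates for means/variances, site-block and
# elliptical-slice updates for the loadings, truncated-normal coordinate
# Gibbs for the propagation field, probit data augmentation and the joint
# (beta, w) draw for the health model, an inverse-Wishart draw for Omega,
# re-interpolation of the exposures to residence locations, and grid/IG
# updates of the GP hyperparameters.
#
# Two exposure-coupling modes are provided.  The default (feedback = FALSE)
# re-draws exposures from their conditional law given the station path with
# no feedback from the outcomes: the "interpolated from the prior
# distributions" two-stage scheme.  With feedback = TRUE the state path,
# the propagation field, the state hypers and the per-location exposure
# draws all carry Metropolis corrections (or extra Gaussian terms) for the
# exposure-site conditionals, making the sweep an exact MCMC kernel for the
# coherent joint model; this mode is what the Geweke joint-distribution
# validation exercises.

#' MCMC configuration
#'
#' @param n_iter total sweeps including burn-in.
#' @param burn_in discarded initial sweeps (`n_iter > burn_in >= 0`).
#' @param thin thinning interval for storage.
#' @param seed master RNG seed (single stream).
#' @param feedback exact joint coupling of exposures and outcomes (see
#'   module notes); default `FALSE` reproduces the two-stage scheme.
#' @param exposure_mode `"sample"` (composition draws, propagating exposure
#'   uncertainty) or `"mean"` (deterministic kriging means).
#' @param seasonal include annual harmonic mean terms per pollutant.
#' @param phi_week range (weeks) of the GP prior on the weekly exposure
#'   coefficients.
#' @param gamma_s2,gamma_phi fixed variance and range of the truncated-GP
#'   prior on the propagation field (`gamma_phi` defaults to half the
#'   station-set diameter).
#' @param ig_prior `c(shape, rate)` inverse-gamma prior for all variances.
#' @param mu_prior_var prior variance of the mean offsets.
#' @param n_grid range-grid size.
#' @param update_hypers Gibbs-update the GP hyperparameters (otherwise they
#'   stay at their initial values).
#' @param ess_reps elliptical-slice steps per diagonal loading field.
#' @param propagation_sweeps coordinate sweeps in the gamma update.
#' @param path_tries FFBS Metropolis attempts per sweep in feedback mode
#'   (each is a valid kernel; more attempts improve path mixing).
#' @param expo_tries per-location exposure Metropolis passes per sweep in
#'   feedback mode.
#' @param store_delta store the station factor path per draw.
#' @param adapt_steps reserved; the sampler has no tuned proposals.
#' @param verbose log progress every 500 sweeps.
#' @export
mcmc_config <- function(n_iter = 25000, burn_in = 5000, thin = 10, seed = 1,
                        feedback = FALSE, exposure_mode = "sample",
                        seasonal = FALSE, phi_week = 2,
                        gamma_s2 = 0.25, gamma_phi = NULL,
                        ig_prior = c(2, 1), mu_prior_var = 100,
                        n_grid = 10L, update_hypers = TRUE, ess_reps = 3L,
                        propagation_sweeps = 10L, path_tries = 1L,
                        expo_tries = 1L, store_delta = TRUE,
                        adapt_steps = 0L, verbose = FALSE) {
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1)
  out <- as.list(environment())
  class(out) <- "mcmc_config"
  out
}

dmvnorm2_log <- function(x, mean, omega) {
  # bivariate normal log density, vectorised over rows of x / mean
  det <- omega[1, 1] * omega[2, 2] - omega[1, 2]^2
  oinv <- matrix(c(omega[2, 2], -omega[1, 2], -omega[1, 2], omega[1, 1]),
                 2, 2) / det
  r <- x - mean
  q <- r[, 1]^2 * oinv[1, 1] + 2 * r[, 1] * r[, 2] * oinv[1, 2] +
    r[, 2]^2 * oinv[2, 2]
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

# weekly-effect GP prior precision over the 6 gestational weeks, repeated
# block-diagonally per factor
weekly_prior_kinv <- function(M, phi_week) {
  d <- abs(outer(GESTATION_WEEKS, GESTATION_WEEKS, "-"))
  kinv <- chol2inv(chol_jitter(exp(-d / phi_week)))
  out <- matrix(0, 6 * M, 6 * M)
  for (m in seq_len(M)) {
    idx <- (m - 1) * 6 + 1:6
    out[idx, idx] <- kinv
  }
  out
}

# Precomputations shared by every sweep
prepare_gibbs_data <- function(panel, cohort, M, config) {
  d <- panel_dims(panel)
  if (M > d$P) stop("number of factors M must not exceed P")
  phi_grid <- range_grid(panel$sites, config$n_grid)
  chol_grid <- lapply(phi_grid, function(phi)
    chol_jitter(correlation_matrix(panel$sites, phi)))
  gamma_phi <- if (is.null(config$gamma_phi))
    max(panel$sites$distances) / 2 else config$gamma_phi
  kinv_gamma <- chol2inv(chol_jitter(
    correlation_matrix(panel$sites, gamma_phi))) / config$gamma_s2
  dat <- list(panel = panel, dims = d, M = M,
              phi_grid = phi_grid, chol_grid = chol_grid,
              gamma_phi = gamma_phi, gamma_s2 = config$gamma_s2,
              kinv_gamma = kinv_gamma,
              free_keys = free_loading_keys(d$P, M))
  if (!is.null(cohort)) {
    dat$cohort <- cohort
    dat$X <- cohort$x
    dat$y <- cohort$y
    dat$week_idx <- gestation_week_index(cohort, panel)
    loc <- exposure_locations(cohort, panel)
    dat$loc <- loc
    dat$K <- nrow(loc$coords)
    dat$krige_grid <- make_krige_cache(panel$sites, loc$coords, phi_grid)
    dat$kg <- krige_weights(panel$sites, loc$coords, gamma_phi)
    dat$w_kinv <- weekly_prior_kinv(M, config$phi_week)
    dat$rho_grid <- seq(-0.99, 0.99, by = 0.005)
    # users of each location: list of (subject, week-slot) index matrices
    dat$loc_users <- lapply(seq_len(dat$K), function(k) {
      which(loc$loc_idx == k, arr.ind = TRUE)
    })
  }
  dat
}

current_hyper_objects <- function(state, dat) {
  list(innovation = gp_hyper(state$s_w2, dat$phi_grid[state$phi_w]),
       delta0 = lapply(seq_len(dat$M), function(m)
         gp_hyper(state$s_d2[m], dat$phi_grid[state$phi_d[m]])),
       gamma = gp_hyper(dat$gamma_s2, dat$gamma_phi))
}

# data-informed initial state (fits start here; Geweke starts from a prior
# draw instead)
init_gibbs_state <- function(dat, config) {
  d <- dat$dims; M <- dat$M
  ybar_net <- function(net) vapply(seq_len(d$P), function(p) {
    v <- dat$panel$Y[, dat$panel$network == net, p]
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  mu_imp <- ybar_net("IMPROVE"); mu_stn <- ybar_net("STN")
  no_imp <- vapply(seq_len(d$P), function(p)
    !any(is.finite(dat$panel$Y[, dat$panel$network == "IMPROVE", p])),
    logical(1))
  mu0 <- ifelse(no_imp, mu_stn, mu_imp)
  ms <- mean_structure(mu0, mu_stn - mu0,
                       amp_cos = if (config$seasonal) rep(0, d$P) else NULL,
                       amp_sin = if (config$seasonal) rep(0, d$P) else NULL)
  resid_var <- vapply(seq_len(d$P), function(p) {
    v <- dat$panel$Y[, , p]; v <- v[is.finite(v)]
    if (length(v) > 1) max(stats::var(v), 1e-3) else 1
  }, numeric(1))
  state <- list(
    ms = ms,
    ev = error_variances(resid_var, resid_var),
    lf = list(log_diag = matrix(0, d$n, M),
              free = stats::setNames(
                lapply(dat$free_keys, function(k) rep(0, d$n)),
                dat$free_keys),
              P = d$P, M = M),
    gamma = matrix(0, d$n, M),
    delta0 = matrix(0, d$n, M),
    delta = array(0, dim = c(d$T, d$n, M)),
    s_w2 = 1, phi_w = ceiling(length(dat$phi_grid) / 2),
    s_d2 = rep(1, M), phi_d = rep(ceiling(length(dat$phi_grid) / 2), M),
    lam_s2 = stats::setNames(
      rep(1, length(dat$free_keys) + M),
      c(dat$free_keys, paste0("d.", seq_len(M)))),
    lam_phi = stats::setNames(
      rep(ceiling(length(dat$phi_grid) / 2), length(dat$free_keys) + M),
      c(dat$free_keys, paste0("d.", seq_len(M)))),
    loglik = NA_real_,
    accept = c(path_prop = 0, path_acc = 0, expo_prop = 0, expo_acc = 0))
  if (!is.null(dat$cohort)) {
    n <- nrow(dat$X); q <- ncol(dat$X)
    state$beta <- matrix(0, q, 2)
    state$wmat <- matrix(0, 6 * M, 2)
    state$omega <- diag(2)
    state$z <- matrix(ifelse(dat$y == 1, 0.5, -0.5), n, 2)
    state$expo <- list(gamma_m = matrix(0, dat$K, M),
                       delta0_m = matrix(0, dat$K, M),
                       w_m = array(0, dim = c(d$T, dat$K, M)),
                       path = array(0, dim = c(d$T + 1, dat$K, M)))
    state$D <- matrix(0, n, 6 * M)
  }
  state
}

# loading hyper list in the format update_loadings() expects
loading_hyper_list <- function(state, dat) {
  keys <- names(state$lam_s2)
  out <- lapply(keys, function(k)
    list(s2 = state$lam_s2[[k]], chol = dat$chol_grid[[state$lam_phi[[k]]]]))
  stats::setNames(out, keys)
}

# exposure kriging pieces at the current ranges
current_krige <- function(state, dat) {
  list(kw = dat$krige_grid[[state$phi_w]],
       kd = lapply(seq_len(dat$M), function(m)
         dat$krige_grid[[state$phi_d[m]]]),
       kg = dat$kg)
}

# One full Gibbs sweep; returns the updated state.
gibbs_sweep <- function(state, dat, config) {
  d <- dat$dims; M <- dat$M
  health <- !is.null(dat$cohort)
  hyp <- current_hyper_objects(state, dat)
  lambda <- constrain_loadings(state$lf$log_diag, state$lf$free, d$P, M)

  ## 1. latent factor path (FFBS).  In feedback mode the retained
  ## exposure residuals are recentered onto the proposed path's kriged
  ## means (unit-Jacobian translation), so the Hastings ratio reduces to
  ## the outcome-likelihood ratio and acceptance stays high.
  n_tries <- if (health && config$feedback) config$path_tries else 1L
  kr <- if (health && config$feedback) current_krige(state, dat)
  for (try in seq_len(n_tries)) {
    prop <- ffbs_factors(dat$panel, state$ms, state$ev, lambda, state$gamma,
                         hyp$innovation, hyp$delta0)
    state$loglik <- prop$loglik
    if (!is.finite(prop$loglik))
      stop("divergence: non-finite observation log-likelihood")
    if (health && config$feedback) {
      state$accept["path_prop"] <- state$accept["path_prop"] + 1
      mu_old <- exposure_means(state$delta0, state$delta, state$gamma,
                               kr$kw, kr$kd)
      mu_new <- exposure_means(prop$delta0, prop$delta, state$gamma,
                               kr$kw, kr$kd)
      expo_prop <- recenter_expo(state$expo, mu_old, mu_new)
      D_prop <- exposure_design(expo_prop$path, dat$loc$loc_idx,
                                dat$week_idx)
      eta_cur <- latent_mean_matrix(state$beta, state$wmat, dat$X, state$D)
      eta_prop <- latent_mean_matrix(state$beta, state$wmat, dat$X, D_prop)
      lr <- sum(dmvnorm2_log(state$z, eta_prop, state$omega)) -
        sum(dmvnorm2_log(state$z, eta_cur, state$omega))
      if (!is.nan(lr) && log(stats::runif(1)) < lr) {
        state$delta0 <- prop$delta0; state$delta <- prop$delta
        state$expo <- expo_prop; state$D <- D_prop
        state$accept["path_acc"] <- state$accept["path_acc"] + 1
      }
    } else {
      state$delta0 <- prop$delta0; state$delta <- prop$delta
    }
  }

  ## 2. error variances
  fit <- fitted_mean_array(dat$panel, state$ms, lambda, state$delta)
  state$ev <- update_error_variances(dat$panel, fit, config$ig_prior)

  ## 3. network mean offsets (and harmonics when enabled)
  factor_fit <- fit - fitted_mean_array(
    dat$panel, state$ms, array(0, dim = dim(lambda)), state$delta)
  state$ms <- update_mean_offsets(dat$panel, state$ms, state$ev, factor_fit,
                                  config$mu_prior_var)

  ## 4. loadings
  state$lf <- update_loadings(dat$panel, state$ms, state$ev, state$lf,
                              state$delta, loading_hyper_list(state, dat),
                              config$ess_reps)
  lambda <- constrain_loadings(state$lf$log_diag, state$lf$free, d$P, M)

  ## 5. propagation field
  q_innov <- chol2inv(dat$chol_grid[[state$phi_w]]) / state$s_w2
  extra <- NULL
  if (health && config$feedback) {
    kr <- current_krige(state, dat)
    extra <- lapply(seq_len(M), function(f) {
      W <- kr$kw$W; v_w <- state$s_w2 * kr$kw$v
      dprev <- t(rbind(state$delta0[, f],
                       matrix(state$delta[, , f], d$T, d$n)[-d$T, ,
                                                            drop = FALSE]))
      qe <- crossprod(W / sqrt(v_w))           # W' V^{-1} W
      S <- tcrossprod(dprev)
      umat <- matrix(state$expo$w_m[, , f], d$T) -
        matrix(state$delta[, , f], d$T) %*% t(W)   # T x K
      us <- sweep(umat, 2, v_w, "/")
      G <- t(W) %*% t(us)                      # n x T
      gv <- dat$gamma_s2 * kr$kg$v
      A_g <- crossprod(kr$kg$W / sqrt(gv))
      b_g <- drop(t(kr$kg$W) %*% (state$expo$gamma_m[, f] / gv))
      list(A = qe * S + A_g,
           b = -rowSums(dprev * G) + b_g,
           logcorr = function(gam) {
             mk <- drop(kr$kg$W %*% gam)
             sdk <- sqrt(gv)
             -sum(log(pmax(stats::pnorm((1 - mk) / sdk) -
                             stats::pnorm((-1 - mk) / sdk), 1e-300)))
           })
    })
  }
  state$gamma <- update_propagation(state$delta0, state$delta, state$gamma,
                                    rep(list(dat$kinv_gamma), M), q_innov,
                                    extra, config$propagation_sweeps)

  if (health) {
    ## 6. probit latent utilities
    eta <- latent_mean_matrix(state$beta, state$wmat, dat$X, state$D)
    state$z <- update_probit_latents(dat$y, eta, state$omega, state$z)

    ## 7. outcome correlation: exact discrete Gibbs on the identified
    ## unit-variance scale (uniform grid prior)
    rho <- as.numeric(update_rho_grid(state$z - eta, dat$rho_grid))
    state$omega <- matrix(c(1, rho, rho, 1), 2, 2)

    ## 8. covariate and weekly-exposure coefficients
    bw <- update_beta_weekly(dat$X, state$D, state$z, state$omega, dat$w_kinv)
    state$beta <- bw$beta; state$wmat <- bw$wmat

    ## 9. exposures at residence locations
    for (pass in seq_len(config$expo_tries))
      state <- update_exposures(state, dat, config)
  }

  ## 10. GP hyperparameters
  if (config$update_hypers)
    state <- update_gp_hypers(state, dat, config)
  state
}

# exposure re-interpolation: joint redraw in two-stage mode, per-location
# independence Metropolis (prior-conditional proposal, outcome-likelihood
# ratio) in feedback mode
update_exposures <- function(state, dat, config) {
  kr <- current_krige(state, dat)
  prop <- draw_exposure_paths(state$delta0, state$delta, state$gamma,
                              state$s_w2, state$s_d2, kr$kw, kr$kd, kr$kg,
                              dat$gamma_s2, config$exposure_mode)
  if (!config$feedback || config$exposure_mode == "mean") {
    state$expo <- prop
    state$D <- exposure_design(prop$path, dat$loc$loc_idx, dat$week_idx)
    return(state)
  }
  eta <- latent_mean_matrix(state$beta, state$wmat, dat$X, state$D)
  for (k in seq_len(dat$K)) {
    state$accept["expo_prop"] <- state$accept["expo_prop"] + 1
    users <- dat$loc_users[[k]]
    if (nrow(users) == 0) {            # location unused: always accept
      state$expo$gamma_m[k, ] <- prop$gamma_m[k, ]
      state$expo$delta0_m[k, ] <- prop$delta0_m[k, ]
      state$expo$w_m[, k, ] <- prop$w_m[, k, ]
      state$expo$path[, k, ] <- prop$path[, k, ]
      state$accept["expo_acc"] <- state$accept["expo_acc"] + 1
      next
    }
    subj <- unique(users[, 1])
    new_expo <- state$expo
    new_expo$gamma_m[k, ] <- prop$gamma_m[k, ]
    new_expo$delta0_m[k, ] <- prop$delta0_m[k, ]
    new_expo$w_m[, k, ] <- prop$w_m[, k, ]
    new_expo$path[, k, ] <- prop$path[, k, ]
    D_new <- state$D
    D_new[subj, ] <- exposure_design(
      new_expo$path, dat$loc$loc_idx[subj, , drop = FALSE],
      dat$week_idx[subj, , drop = FALSE])
    eta_new <- latent_mean_matrix(state$beta, state$wmat,
                                  dat$X[subj, , drop = FALSE],
                                  D_new[subj, , drop = FALSE])
    lr <- sum(dmvnorm2_log(state$z[subj, , drop = FALSE], eta_new,
                           state$omega)) -
      sum(dmvnorm2_log(state$z[subj, , drop = FALSE],
                       eta[subj, , drop = FALSE], state$omega))
    if (!is.nan(lr) && log(stats::runif(1)) < lr) {
      state$expo <- new_expo
      state$D <- D_new
      eta[subj, ] <- eta_new
      state$accept["expo_acc"] <- state$accept["expo_acc"] + 1
    }
  }
  state
}

# grid/IG updates of the state-process and loading hyperparameters.
# In feedback mode the innovation/initial-state variance and range moves
# are proposed from their station-only conditionals with the retained
# exposure residuals rescaled/recentered to the proposed value (the scale
# factors cancel the Gaussian densities in the Hastings ratio), accepted
# by the outcome-likelihood ratio.
update_gp_hypers <- function(state, dat, config) {
  d <- dat$dims; M <- dat$M
  health_fb <- !is.null(dat$cohort) && config$feedback
  innov <- station_innovations(state$delta0, state$delta, state$gamma)

  ## innovation variance (shared across factors): station-only conditional
  quad <- 0
  for (m in seq_len(M))
    quad <- quad + sum(corr_quad(dat$chol_grid[[state$phi_w]],
                                 t(matrix(innov[, , m], d$T, d$n))))
  s_w2_prop <- update_gp_variance(quad, d$T * d$n * M, config$ig_prior)
  if (!health_fb) {
    state$s_w2 <- s_w2_prop
  } else {
    state <- mh_hyper_expo(state, dat, s_w2 = s_w2_prop)
  }

  ## innovation range
  fields_w <- do.call(cbind, lapply(seq_len(M), function(m)
    t(matrix(innov[, , m], d$T, d$n))))
  phi_w_prop <- as.integer(update_gp_range(fields_w, state$s_w2,
                                           dat$chol_grid))
  if (!health_fb) {
    state$phi_w <- phi_w_prop
  } else {
    state <- mh_hyper_expo(state, dat, phi_w = phi_w_prop)
  }

  ## initial-state hypers per factor
  for (m in seq_len(M)) {
    quad <- sum(corr_quad(dat$chol_grid[[state$phi_d[m]]], state$delta0[, m]))
    s_d2_prop <- state$s_d2
    s_d2_prop[m] <- update_gp_variance(quad, d$n, config$ig_prior)
    if (!health_fb) {
      state$s_d2 <- s_d2_prop
    } else {
      state <- mh_hyper_expo(state, dat, s_d2 = s_d2_prop)
    }
    phi_prop <- state$phi_d
    phi_prop[m] <- as.integer(update_gp_range(state$delta0[, m],
                                              state$s_d2[m], dat$chol_grid))
    if (!health_fb) {
      state$phi_d <- phi_prop
    } else {
      state <- mh_hyper_expo(state, dat, phi_d = phi_prop)
    }
  }

  ## loading-field hypers (plain GP fields; no exposure coupling)
  for (key in names(state$lam_s2)) {
    fld <- if (startsWith(key, "d.")) {
      state$lf$log_diag[, as.integer(substring(key, 3))]
    } else {
      v <- state$lf$free[[key]]
      if (is.null(v)) rep(0, d$n) else v
    }
    quad <- sum(corr_quad(dat$chol_grid[[state$lam_phi[[key]]]], fld))
    state$lam_s2[[key]] <- update_gp_variance(quad, d$n, config$ig_prior)
    state$lam_phi[[key]] <- as.integer(update_gp_range(fld,
                                                       state$lam_s2[[key]],
                                                       dat$chol_grid))
  }
  state
}

# recentering Metropolis move for one state-process hyperparameter in
# feedback mode: the proposal comes from the station-only conditional,
# the retained exposure residuals are mapped onto the proposed
# conditional law (mean shift for ranges, scale for variances), and the
# outcome-likelihood ratio decides acceptance.
mh_hyper_expo <- function(state, dat, s_w2 = state$s_w2,
                          phi_w = state$phi_w, s_d2 = state$s_d2,
                          phi_d = state$phi_d) {
  kw_old <- dat$krige_grid[[state$phi_w]]
  kd_old <- lapply(seq_len(dat$M), function(m)
    dat$krige_grid[[state$phi_d[m]]])
  kw_new <- dat$krige_grid[[phi_w]]
  kd_new <- lapply(seq_len(dat$M), function(m) dat$krige_grid[[phi_d[m]]])
  mu_old <- exposure_means(state$delta0, state$delta, state$gamma,
                           kw_old, kd_old)
  mu_new <- exposure_means(state$delta0, state$delta, state$gamma,
                           kw_new, kd_new)
  scale_w <- sqrt((s_w2 * kw_new$v) / (state$s_w2 * kw_old$v))
  scale_d0 <- vapply(seq_len(dat$M), function(m)
    sqrt((s_d2[m] * kd_new[[m]]$v) / (state$s_d2[m] * kd_old[[m]]$v)),
    numeric(dat$K))
  expo_prop <- recenter_expo(state$expo, mu_old, mu_new, scale_w,
                             matrix(scale_d0, dat$K, dat$M))
  D_prop <- exposure_design(expo_prop$path, dat$loc$loc_idx, dat$week_idx)
  eta_cur <- latent_mean_matrix(state$beta, state$wmat, dat$X, state$D)
  eta_prop <- latent_mean_matrix(state$beta, state$wmat, dat$X, D_prop)
  lr <- sum(dmvnorm2_log(state$z, eta_prop, state$omega)) -
    sum(dmvnorm2_log(state$z, eta_cur, state$omega))
  if (!is.nan(lr) && log(stats::runif(1)) < lr) {
    state$s_w2 <- s_w2; state$phi_w <- phi_w
    state$s_d2 <- s_d2; state$phi_d <- phi_d
    state$expo <- expo_prop; state$D <- D_prop
  }
  state
}

flatten_state <- function(state, dat, config) {
  out <- c(mu0 = list(state$ms$mu0), mu1 = list(state$ms$mu1),
           sigma2_stn = list(state$ev$sigma2_stn),
           sigma2_imp = list(state$ev$sigma2_imp),
           log_diag = list(as.numeric(state$lf$log_diag)),
           free_loadings = list(as.numeric(do.call(
             cbind, c(state$lf$free, list(matrix(0, dat$dims$n, 0)))))),
           gamma = list(as.numeric(state$gamma)),
           s_w2 = list(state$s_w2), phi_w = list(dat$phi_grid[state$phi_w]),
           s_d2 = list(state$s_d2),
           phi_d = list(dat$phi_grid[state$phi_d]),
           loglik = list(state$loglik))
  if (config$seasonal) {
    out$amp_cos <- state$ms$amp_cos
    out$amp_sin <- state$ms$amp_sin
  }
  if (config$store_delta) {
    out$delta0 <- as.numeric(state$delta0)
    out$delta <- as.numeric(state$delta)
  }
  if (!is.null(dat$cohort)) {
    out$beta <- as.numeric(state$beta)
    out$w <- as.numeric(state$wmat)
    out$omega <- as.numeric(state$omega)
    out$z <- as.numeric(state$z)
    out$exposure <- as.numeric(state$D)
  }
  out
}

#' Fit the joint pollutant/birth-defect model by MCMC
#'
#' Runs the Gibbs sampler described in the package vignette, storing
#' thinned posterior draws of every parameter block plus the interpolated
#' exposures.  Fully reproducible given `config$seed`.
#'
#' @param panel a [pollutant_panel()].
#' @param cohort a [cohort_table()], or `NULL` to fit the pollutant model
#'   alone.
#' @param M number of latent factors.
#' @param config an [mcmc_config()].
#' @return an object of class `pm_fit`: list with `draws` (named list of
#'   draw matrices, one row per stored draw), `accept` rates, dimensions
#'   and labels, and the configuration.
#' @export
run_gibbs <- function(panel, cohort = NULL, M = 1, config = mcmc_config()) {
  stopifnot(inherits(config, "mcmc_config"))
  set.seed(config$seed)
  dat <- prepare_gibbs_data(panel, cohort, M, config)
  state <- init_gibbs_state(dat, config)
  if (!is.null(cohort)) {
    # initial exposure interpolation so the first health updates see a
    # non-degenerate design
    kr <- current_krige(state, dat)
    state$expo <- draw_exposure_paths(state$delta0, state$delta, state$gamma,
                                      state$s_w2, state$s_d2, kr$kw, kr$kd,
                                      kr$kg, dat$gamma_s2,
                                      config$exposure_mode)
    state$D <- exposure_design(state$expo$path, dat$loc$loc_idx, dat$week_idx)
  }
  n_store <- floor((config$n_iter - config$burn_in) / config$thin)
  store <- NULL
  si <- 0L
  for (it in seq_len(config$n_iter)) {
    state <- gibbs_sweep(state, dat, config)
    if (config$verbose && it %% 500L == 0L)
      message(sprintf("[%s] sweep %d/%d loglik %.2f",
                      format(Sys.time(), "%H:%M:%S"), it, config$n_iter,
                      state$loglik))
    if (it > config$burn_in &&
        (it - config$burn_in) %% config$thin == 0L && si < n_store) {
      fs <- flatten_state(state, dat, config)
      if (is.null(store)) {
        store <- lapply(fs, function(v)
          matrix(NA_real_, n_store, length(v)))
      }
      si <- si + 1L
      for (nm in names(fs)) store[[nm]][si, ] <- fs[[nm]]
    }
  }
  acc <- state$accept
  structure(list(draws = store, n_draws = n_store, M = M,
                 dims = dat$dims, phi_grid = dat$phi_grid,
                 pollutant_names = panel$pollutant_names,
                 covariate_names = if (!is.null(cohort)) colnames(cohort$x),
                 N = if (!is.null(cohort)) length(cohort$ids),
                 accept = c(
                   path = if (acc["path_prop"] > 0)
                     unname(acc["path_acc"] / acc["path_prop"]) else NA_real_,
                   exposure = if (acc["expo_prop"] > 0)
                     unname(acc["expo_acc"] / acc["expo_prop"]) else NA_real_),
                 config = config),
            class = "pm_fit")
}

#' @export
print.pm_fit <- function(x, ...) {
  cat(sprintf("<pm_fit> M = %d factors, %d stored draws (%d sweeps, burn-in %d, thin %d)\n",
              x$M, x$n_draws, x$config$n_iter, x$config$burn_in,
              x$config$thin))
  if (!is.na(x$accept["path"]))
    cat(sprintf("  feedback acceptance: path %.2f, exposure %.2f\n",
                x$accept["path"], x$accept["exposure"]))
  invisible(x)
}

#' Posterior-predictive marginal defect probabilities
#'
#' Per subject and defect, the posterior mean of `Phi(eta_ij /
#' sqrt(Omega_jj))` over the stored draws (unit-variance reporting scale).
#'
#' @param fit a [run_gibbs()] result fitted with a cohort.
#' @param X,D optional design/exposure matrices (default: the stored
#'   exposures and the fit's cohort design are reconstructed from draws;
#'   pass explicitly for new subjects).
#' @param cohort the cohort the fit used.
#' @return `N x 2` matrix of probabilities.
#' @export
predictive_probs <- function(fit, cohort) {
  dr <- fit$draws
  if (is.null(dr$beta)) stop("fit has no health-model draws")
  n <- fit$N; q <- length(fit$covariate_names); M <- fit$M
  S <- nrow(dr$beta)
  acc <- matrix(0, n, 2)
  for (s in seq_len(S)) {
    beta <- matrix(dr$beta[s, ], q, 2)
    wmat <- matrix(dr$w[s, ], 6 * M, 2)
    omega <- matrix(dr$omega[s, ], 2, 2)
    D <- matrix(dr$exposure[s, ], n, 6 * M)
    eta <- latent_mean_matrix(beta, wmat, cohort$x, D)
    acc <- acc + stats::pnorm(sweep(eta, 2, sqrt(diag(omega)), "/"))
  }
  acc / S
}
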