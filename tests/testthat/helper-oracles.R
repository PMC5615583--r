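# Shared fixtures and independent oracles used across the suite.

# small fixed site layouts
toy_sites <- function(n = 4) {
  set.seed(100 + n)
  spatial_sites_xy(paste0("s", seq_len(n)),
                   x = stats::runif(n, 0, 300),
                   y = stats::runif(n, 0, 300))
}

# brute-force joint-Gaussian conditional: full covariance of the stacked
# state path x = (delta_0, ..., delta_T) (factor-major within time) plus
# observations, conditioned directly.  Dimensions are kept tiny.
state_path_joint <- function(G, W, C0, T) {
  d <- nrow(W)
  n_tot <- d * (T + 1)
  Sigma <- matrix(0, n_tot, n_tot)
  blk <- function(t) (t * d) + seq_len(d)   # t = 0..T
  # marginal covariances by recursion, cross-covariances via powers of G
  V <- vector("list", T + 1)
  V[[1]] <- C0
  for (t in seq_len(T)) V[[t + 1]] <- G %*% V[[t]] %*% t(G) + W
  for (t in 0:T) {
    Sigma[blk(t), blk(t)] <- V[[t + 1]]
    if (t < T) {
      Gp <- diag(d)
      for (s in (t + 1):T) {
        Gp <- G %*% Gp
        Sigma[blk(s), blk(t)] <- Gp %*% V[[t + 1]]
        Sigma[blk(t), blk(s)] <- t(Sigma[blk(s), blk(t)])
      }
    }
  }
  Sigma
}

# oracle posterior moments of the state path given panel observations
ffbs_oracle <- function(panel, ms, ev, lambda, gamma, innovation_hyper,
                        delta0_hyper) {
  d <- dsfm:::panel_dims(panel)
  M <- dim(lambda)[3]
  corr_w <- correlation_matrix(panel$sites, innovation_hyper$range)
  W <- dsfm:::stacked_state_cov(rep(list(corr_w), M),
                                rep(innovation_hyper$variance, M))
  C0 <- dsfm:::stacked_state_cov(
    lapply(delta0_hyper, function(h)
      correlation_matrix(panel$sites, h$range)),
    vapply(delta0_hyper, `[[`, numeric(1), "variance"))
  G <- diag(as.numeric(gamma), d$n * M)
  Sx <- state_path_joint(G, W, C0, d$T)
  H <- dsfm:::loading_obs_matrix(lambda)
  mu <- dsfm:::observation_mean_matrix(panel, ms)        # T x nP
  yv <- as.numeric(t(dsfm:::panel_obs_matrix(panel)))    # stacked by time
  # build full observation operator on the path vector
  d_state <- d$n * M
  Hfull <- matrix(0, d$T * nrow(H), d_state * (d$T + 1))
  muv <- numeric(d$T * nrow(H))
  for (t in seq_len(d$T)) {
    rows <- (t - 1) * nrow(H) + seq_len(nrow(H))
    cols <- t * d_state + seq_len(d_state)
    Hfull[rows, cols] <- H
    muv[rows] <- mu[t, ]
  }
  yv2 <- as.numeric(dsfm:::panel_obs_matrix(panel))      # column-major: cell-major
  # reorder: panel_obs_matrix is T x (nP); we need time-major stacking
  Ym <- dsfm:::panel_obs_matrix(panel)
  yv <- as.numeric(t(Ym))
  obs <- which(is.finite(yv))
  R <- diag(rep(as.numeric(dsfm:::variance_matrix(ev, panel$network)), d$T))
  Ho <- Hfull[obs, , drop = FALSE]
  Ro <- R[obs, obs, drop = FALSE]
  S <- Ho %*% Sx %*% t(Ho) + Ro
  K <- Sx %*% t(Ho) %*% solve(S)
  mean_post <- drop(K %*% (yv[obs] - muv[obs]))
  cov_post <- Sx - K %*% Ho %*% Sx
  list(mean = mean_post, cov = cov_post, d_state = d_state)
}

# numerical-integration oracle for the bivariate normal CDF
pbvnorm_oracle <- function(h, k, rho) {
  if (!is.finite(h) || !is.finite(k)) stop("finite limits only")
  f <- function(x)
    stats::pnorm((k - rho * x) / sqrt(1 - rho^2)) * stats::dnorm(x)
  stats::integrate(f, -Inf, h, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# micro synthetic study shared by several tests
micro_study <- function(seed = 1, n_total = 10, n_study = 6, T_weeks = 30,
                        n_cases = 30, n_controls = 50, ...) {
  st <- generate_stations(n_total = n_total, n_study = n_study, seed = seed)
  tr <- make_truth("toy", ...)
  sim <- generate_pollution(st, tr, T_weeks = T_weeks, seed = seed + 1)
  co <- generate_cohort(sim, n_cases = n_cases, n_controls = n_controls,
                        seed = seed + 2)
  list(stations = st, truth = sim$truth, sim = sim, cohort = co)
}
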