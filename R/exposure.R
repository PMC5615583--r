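# Interpolation of the latent factor process to mothers' residences.
#
# Conditional on the station-site state path, each residence location's
# factor path follows the composition law: kriged initial state, kriged
# innovation per week, and a truncated-normal conditional draw of the
# local propagation coefficient, then the AR recursion.  Locations are
# treated as conditionally independent of one another given the station
# path (per-location conditional law); this matches the synthetic-data
# generator exactly and keeps per-mother Metropolis corrections tractable
# in feedback mode.

# unique residence locations over the cohort, projected with the panel's
# station projection; returns K x 2 coords and the N x 6 location index
exposure_locations <- function(cohort, panel) {
  res <- cohort$residences
  n <- dim(res)[1]
  lon <- as.numeric(res[, , 1]); lat <- as.numeric(res[, , 2])
  key <- paste(signif(lon, 10), signif(lat, 10))
  uk <- !duplicated(key)
  coords <- if (!is.null(panel$sites$origin))
    project_equirect(lon[uk], lat[uk],
                     panel$sites$origin[1], panel$sites$origin[2])
  else cbind(x = lon[uk], y = lat[uk])
  list(coords = coords,
       loc_idx = matrix(match(key, key[uk]), n, 6))
}

# kriging weight caches for a set of target coords over a range grid
make_krige_cache <- function(sites, coords, phi_values, kernel = "exponential") {
  lapply(phi_values, function(phi) krige_weights(sites, coords, phi, kernel))
}

# station innovations w_t = delta_t - gamma * delta_{t-1}, T x n x M
station_innovations <- function(delta0, delta, gamma) {
  tt <- dim(delta)[1]; n <- dim(delta)[2]; M <- dim(delta)[3]
  prev <- array(0, dim = dim(delta))
  prev[1, , ] <- delta0
  if (tt > 1) prev[-1, , ] <- delta[-tt, , , drop = FALSE]
  gam <- aperm(array(gamma, dim = c(n, M, tt)), c(3, 1, 2))
  delta - gam * prev
}

#' Draw (or evaluate) factor paths at residence locations
#'
#' Composition sampling of the latent factor process at `K` new locations
#' given the station-site draw: the initial state and each week's
#' innovation are kriged to the new locations and drawn from their
#' conditional normals, the local propagation coefficient from its
#' truncated-normal conditional, and the AR recursion propagates.  In
#' `"mean"` mode conditional means are used throughout (deterministic
#' kriging interpolation).
#'
#' @param delta0 `n x M` initial station state; `delta` `T x n x M` path;
#'   `gamma` `n x M` station propagation field.
#' @param s_w2,s_d2 innovation variance (scalar) and per-factor initial
#'   variances.
#' @param kw,kd,kg kriging weight sets (`list(W, v)`) for the innovation,
#'   initial-state and propagation fields at the target locations.
#' @param gamma_s2 marginal variance of the propagation field.
#' @param mode `"sample"` or `"mean"`.
#' @return list with `gamma_m` (`K x M`), `delta0_m` (`K x M`), `w_m`
#'   (`T x K x M`) and `path` (`(T+1) x K x M`, week 0 first).
#' @export
draw_exposure_paths <- function(delta0, delta, gamma, s_w2, s_d2,
                                kw, kd, kg, gamma_s2,
                                mode = c("sample", "mean")) {
  mode <- match.arg(mode)
  tt <- dim(delta)[1]; M <- dim(delta)[3]
  K <- nrow(kw$W)
  innov <- station_innovations(delta0, delta, gamma)
  gamma_m <- matrix(0, K, M)
  delta0_m <- matrix(0, K, M)
  w_m <- array(0, dim = c(tt, K, M))
  path <- array(0, dim = c(tt + 1, K, M))
  for (m in seq_len(M)) {
    gmean <- drop(kg$W %*% gamma[, m])
    gsd <- sqrt(gamma_s2 * kg$v)
    gamma_m[, m] <- if (mode == "sample")
      rtnorm(K, gmean, gsd, -1, 1) else etnorm(gmean, gsd, -1, 1)
    d0mean <- drop(kd[[m]]$W %*% delta0[, m])
    d0sd <- sqrt(s_d2[m] * kd[[m]]$v)
    delta0_m[, m] <- if (mode == "sample")
      stats::rnorm(K, d0mean, d0sd) else d0mean
    # innov[, , m] is T x n; kriged means are T x K
    wmean <- matrix(innov[, , m], tt) %*% t(kw$W)
    w_m[, , m] <- if (mode == "sample")
      wmean + matrix(stats::rnorm(tt * K), tt, K) *
        matrix(sqrt(s_w2 * kw$v), tt, K, byrow = TRUE)
    else wmean
    path[1, , m] <- delta0_m[, m]
    for (t in seq_len(tt))
      path[t + 1, , m] <- gamma_m[, m] * path[t, , m] + w_m[t, , m]
  }
  list(gamma_m = gamma_m, delta0_m = delta0_m, w_m = w_m, path = path)
}

# N x 6M exposure design from a location path: D[i, (m-1)*6 + l] =
# path[week_idx[i, l] + 1, loc_idx[i, l], m]
exposure_design <- function(path, loc_idx, week_idx) {
  n <- nrow(loc_idx); M <- dim(path)[3]
  D <- matrix(0, n, 6 * M)
  for (m in seq_len(M)) for (l in 1:6) {
    D[, (m - 1) * 6 + l] <- path[cbind(week_idx[, l] + 1L, loc_idx[, l],
                                       rep(m, n))]
  }
  D
}

#' Extract weekly exposures for a cohort from a factor-field draw
#'
#' Interpolates one posterior (or generated) draw of the factor state to
#' every subject's residence for gestational weeks 3-8.  With
#' `mode = "mean"` this is deterministic kriging: a subject living exactly
#' at a station receives that station's factor path.
#'
#' @param cohort a [cohort_table()].
#' @param panel the [pollutant_panel()] the state refers to.
#' @param delta0,delta,gamma station-site state draw.
#' @param innovation_hyper,delta0_hyper,gamma_hyper GP hyperparameters
#'   ([gp_hyper()]; `delta0_hyper` a list of M).
#' @param mode `"sample"` for a conditional draw, `"mean"` for kriging
#'   means.
#' @param kernel correlation kernel.
#' @return `N x 6 x M` exposure array `delta_{ilm}`.
#' @export
extract_exposures <- function(cohort, panel, delta0, delta, gamma,
                              innovation_hyper, delta0_hyper, gamma_hyper,
                              mode = c("sample", "mean"),
                              kernel = "exponential") {
  mode <- match.arg(mode)
  M <- dim(delta)[3]
  week_idx <- gestation_week_index(cohort, panel)
  loc <- exposure_locations(cohort, panel)
  kw <- krige_weights(panel$sites, loc$coords, innovation_hyper$range, kernel)
  kd <- lapply(delta0_hyper, function(h)
    krige_weights(panel$sites, loc$coords, h$range, kernel))
  kg <- krige_weights(panel$sites, loc$coords, gamma_hyper$range, kernel)
  expo <- draw_exposure_paths(delta0, delta, gamma,
                              innovation_hyper$variance,
                              vapply(delta0_hyper, `[[`, numeric(1), "variance"),
                              kw, kd, kg, gamma_hyper$variance, mode)
  D <- exposure_design(expo$path, loc$loc_idx, week_idx)
  array(D, dim = c(nrow(D), 6, M))
}

# kriged conditional means of the exposure components given a station
# state: per factor, w (T x K) and d0 (K)
exposure_means <- function(delta0, delta, gamma, kw, kd) {
  tt <- dim(delta)[1]; M <- dim(delta)[3]
  innov <- station_innovations(delta0, delta, gamma)
  list(w = lapply(seq_len(M), function(m)
         matrix(innov[, , m], tt) %*% t(kw$W)),
       d0 = lapply(seq_len(M), function(m) drop(kd[[m]]$W %*% delta0[, m])))
}

# translate/rescale retained exposure residuals onto new conditional means
# (used by the recentering Metropolis moves for the state path and the
# state-process hyperparameters; unit-Jacobian up to the scale factors,
# which cancel against the Gaussian densities in the Hastings ratio)
recenter_expo <- function(expo, mu_old, mu_new, scale_w = 1, scale_d0 = 1) {
  tt <- dim(expo$w_m)[1]; K <- dim(expo$w_m)[2]; M <- dim(expo$w_m)[3]
  for (m in seq_len(M)) {
    sw_m <- if (is.matrix(scale_w)) scale_w[, m] else scale_w
    sd0_m <- if (is.matrix(scale_d0)) scale_d0[, m] else scale_d0
    sw <- matrix(rep_len(sw_m, K), tt, K, byrow = TRUE)
    sd0 <- rep_len(sd0_m, K)
    expo$w_m[, , m] <- mu_new$w[[m]] +
      sw * (matrix(expo$w_m[, , m], tt) - mu_old$w[[m]])
    expo$delta0_m[, m] <- mu_new$d0[[m]] +
      sd0 * (expo$delta0_m[, m] - mu_old$d0[[m]])
    expo$path[1, , m] <- expo$delta0_m[, m]
    for (t in seq_len(tt))
      expo$path[t + 1, , m] <- expo$gamma_m[, m] * expo$path[t, , m] +
        expo$w_m[t, , m]
  }
  expo
}
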