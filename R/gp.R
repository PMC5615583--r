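# Gaussian-process primitives shared by every spatial prior in the model:
# isotropic correlation kernels on planar-km coordinates, unconditional and
# box-truncated sampling, and exact conditional (kriging) prediction.

EARTH_RADIUS_KM <- 6371

#' Project longitude/latitude to planar kilometres
#'
#' Equirectangular projection about a reference point.  Adequate for
#' regional extents of a few hundred kilometres (distortion below 1% over a
#' California-sized domain), and keeps isotropic covariance kernels valid on
#' the resulting Euclidean distances.
#'
#' @param lon,lat numeric vectors of geographic coordinates in degrees.
#' @param lon0,lat0 projection origin in degrees.
#' @return a two-column matrix of `x`, `y` coordinates in kilometres.
#' @export
project_equirect <- function(lon, lat, lon0, lat0) {
  rad <- pi / 180
  cbind(x = EARTH_RADIUS_KM * cos(lat0 * rad) * (lon - lon0) * rad,
        y = EARTH_RADIUS_KM * (lat - lat0) * rad)
}

#' Spatial site set
#'
#' Container for monitoring-station (or residence) locations: identifiers,
#' planar coordinates in kilometres, and the full Euclidean distance matrix.
#' Geographic input is projected with [project_equirect()]; the projection
#' origin is stored so that later locations (e.g. residences) can be
#' projected consistently with [spatial_sites()]'s `origin` argument.
#'
#' @param ids site identifiers (coerced to character).
#' @param lon,lat geographic coordinates in degrees.
#' @param origin optional `c(lon, lat)` projection origin; defaults to the
#'   centroid of the input coordinates.
#' @return an object of class `spatial_sites` with fields `ids`, `coords`
#'   (n x 2 km), `lonlat`, `origin` and `distances` (n x n km).
#' @export
spatial_sites <- function(ids, lon, lat, origin = NULL) {
  stopifnot(length(ids) == length(lon), length(lon) == length(lat))
  lon <- as.numeric(lon); lat <- as.numeric(lat)
  if (!all(is.finite(lon)) || !all(is.finite(lat)))
    stop("site coordinates must be finite")
  if (is.null(origin)) origin <- c(mean(lon), mean(lat))
  xy <- project_equirect(lon, lat, origin[1], origin[2])
  new_spatial_sites(as.character(ids), xy, cbind(lon = lon, lat = lat), origin)
}

#' Spatial site set from planar coordinates
#'
#' As [spatial_sites()] but for coordinates already on a planar kilometre
#' grid (used for abstract simulation domains and unit tests).
#'
#' @param ids site identifiers.
#' @param x,y planar coordinates in kilometres.
#' @export
spatial_sites_xy <- function(ids, x, y) {
  stopifnot(length(ids) == length(x), length(x) == length(y))
  x <- as.numeric(x); y <- as.numeric(y)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("site coordinates must be finite")
  new_spatial_sites(as.character(ids), cbind(x = x, y = y), NULL, NULL)
}

new_spatial_sites <- function(ids, coords, lonlat, origin) {
  rownames(coords) <- NULL
  d <- unname(as.matrix(stats::dist(coords)))
  structure(list(ids = ids, coords = coords, lonlat = lonlat,
                 origin = origin, distances = d),
            class = "spatial_sites")
}

#' @export
print.spatial_sites <- function(x, ...) {
  cat(sprintf("<spatial_sites> %d sites, extent %.1f km\n",
              length(x$ids), max(x$distances)))
  invisible(x)
}

n_sites <- function(sites) length(sites$ids)

#' Gaussian-process hyperparameters
#'
#' A (variance, range) pair for an isotropic GP.  Variance is in squared
#' units of the field, range in kilometres (or weeks, for the gestational
#' time axis).  `variance = 0` is allowed and denotes a degenerate
#' (point-mass) process.
#'
#' @param variance marginal variance, `>= 0`.
#' @param range correlation range, `> 0`.
#' @export
gp_hyper <- function(variance, range) {
  if (!is.numeric(variance) || length(variance) != 1L || !is.finite(variance) ||
      variance < 0)
    stop("invalid GP hyperparameter: variance must be a nonnegative number")
  if (!is.numeric(range) || length(range) != 1L || !is.finite(range) ||
      range <= 0)
    stop("invalid GP hyperparameter: range must be a positive number")
  structure(list(variance = variance, range = range), class = "gp_hyper")
}

corr_kernel <- function(d, range, kernel = c("exponential", "matern32")) {
  kernel <- match.arg(kernel)
  switch(kernel,
         exponential = exp(-d / range),
         matern32 = {
           a <- sqrt(3) * d / range
           (1 + a) * exp(-a)
         })
}

#' Spatial correlation matrix
#'
#' Correlation matrix `R(phi)` over a site set for an isotropic kernel.  The
#' default is the exponential kernel `exp(-d/phi)`; a Matern-3/2
#' alternative is available.
#'
#' @param sites a [spatial_sites()] object.
#' @param range correlation range in km, `> 0`.
#' @param kernel `"exponential"` (default) or `"matern32"`.
#' @return an n x n correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(sites, range, kernel = "exponential") {
  if (!is.numeric(range) || length(range) != 1L || !is.finite(range) ||
      range <= 0)
    stop("invalid parameter: range must be a positive number")
  corr_kernel(sites$distances, range, kernel)
}

cross_distances <- function(coords_a, coords_b) {
  dx <- outer(coords_a[, 1], coords_b[, 1], "-")
  dy <- outer(coords_a[, 2], coords_b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

# Cholesky with escalating diagonal jitter (relative to mean diagonal).
# A tiny base jitter (1e-10 relative) is always added for SPD robustness
# without disturbing oracle-level accuracy; genuinely ill-conditioned
# matrices escalate silently to 1e-8 and then with a warning beyond it.
chol_jitter <- function(sigma, rel = 1e-10, max_tries = 7L) {
  n <- nrow(sigma)
  scale <- mean(diag(sigma))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  jit <- rel * scale
  for (k in seq_len(max_tries)) {
    u <- tryCatch(chol(sigma + diag(jit, n)), error = function(e) NULL)
    if (!is.null(u)) {
      if (k > 2L) warning("covariance numerically stabilized with jitter ",
                          signif(jit, 3))
      return(u)
    }
    jit <- jit * 100
  }
  stop("covariance matrix is not positive definite even after jitter")
}

mvn_sample <- function(mean, sigma) {
  u <- chol_jitter(sigma)
  drop(mean + crossprod(u, stats::rnorm(nrow(sigma))))
}

#' Sample a Gaussian-process realisation over a site set
#'
#' Draws from `N(mean, variance * R(range))`.  With `variance = 0` the mean
#' is returned exactly.  Reproducible under `set.seed()`.
#'
#' @param sites a [spatial_sites()] object.
#' @param hyper a [gp_hyper()] object.
#' @param mean scalar or n-vector mean.
#' @param kernel correlation kernel, see [correlation_matrix()].
#' @return an n-vector.
#' @export
gp_sample <- function(sites, hyper, mean = 0, kernel = "exponential") {
  stopifnot(inherits(hyper, "gp_hyper"))
  n <- n_sites(sites)
  mu <- rep_len(mean, n)
  if (hyper$variance == 0) return(mu)
  sigma <- hyper$variance * correlation_matrix(sites, hyper$range, kernel)
  mvn_sample(mu, sigma)
}

#' Gaussian-process conditional (kriging) prediction
#'
#' Exact Gaussian conditional mean and covariance of a zero-mean GP at new
#' locations given observed values, with optional observation nugget.
#'
#' @param obs_sites,new_sites [spatial_sites()] objects on a common
#'   projection.
#' @param obs_values observed field values at `obs_sites`.
#' @param hyper a [gp_hyper()] object.
#' @param nugget nonnegative observation-error variance added to the
#'   observed-site covariance diagonal.
#' @param kernel correlation kernel.
#' @return `list(mean, cov)`: predictive mean vector and covariance matrix
#'   at `new_sites`.
#' @export
krige_conditional <- function(obs_sites, obs_values, new_sites, hyper,
                              nugget = 0, kernel = "exponential") {
  stopifnot(inherits(hyper, "gp_hyper"), nugget >= 0)
  obs_values <- as.numeric(obs_values)
  if (!all(is.finite(obs_values))) stop("observed values must be finite")
  n <- n_sites(obs_sites); m <- n_sites(new_sites)
  if (n < 1L || m < 1L) stop("site sets must be non-empty")
  if (length(obs_values) != n)
    stop("obs_values length does not match obs_sites")
  if (!is.null(obs_sites$origin) && !is.null(new_sites$origin) &&
      any(abs(obs_sites$origin - new_sites$origin) > 1e-9))
    stop("site sets use different projection origins")
  if (nugget == 0) {
    dup <- which(obs_sites$distances < 1e-9 &
                 abs(outer(obs_values, obs_values, "-")) > 1e-8, arr.ind = TRUE)
    if (nrow(dup) > 0)
      stop("ill-conditioned kriging system: duplicate observation sites ",
           "with conflicting values and zero nugget")
  }
  if (hyper$variance == 0)
    return(list(mean = rep(0, m), cov = matrix(0, m, m)))
  k_obs <- hyper$variance * correlation_matrix(obs_sites, hyper$range, kernel) +
    diag(nugget, n)
  k_cross <- hyper$variance *
    corr_kernel(cross_distances(obs_sites$coords, new_sites$coords),
                hyper$range, kernel)
  k_new <- hyper$variance * correlation_matrix(new_sites, hyper$range, kernel)
  u <- chol_jitter(k_obs)
  a <- backsolve(u, forwardsolve(t(u), cbind(obs_values, k_cross)))
  mean_new <- unname(drop(crossprod(k_cross, a[, 1L])))
  cov_new <- k_new - crossprod(k_cross, a[, -1L, drop = FALSE])
  cov_new <- unname((cov_new + t(cov_new)) / 2)
  list(mean = mean_new, cov = cov_new)
}

# Kriging weight precomputation on the unit-variance correlation scale:
# W = C_cross' K^{-1} (m x n) and conditional variance scale
# v = 1 - diag(W C_cross) (length m), so that for a field with marginal
# variance s2 the conditional law at new site j is
# N((W y)_j, s2 * v_j).  Used heavily by the exposure interpolator.
krige_weights <- function(obs_sites, new_coords, range, kernel = "exponential") {
  r_obs <- correlation_matrix(obs_sites, range, kernel)
  c_cross <- corr_kernel(cross_distances(obs_sites$coords, new_coords),
                         range, kernel)
  u <- chol_jitter(r_obs)
  w <- t(backsolve(u, forwardsolve(t(u), c_cross)))   # m x n
  v <- pmax(1 - rowSums(w * t(c_cross)), 1e-12)
  list(W = w, v = v)
}

#' Stable truncated-normal sampler
#'
#' Vectorised exact sampling from `N(mean, sd^2)` truncated to
#' `(lower, upper)` by inverse-CDF in log space, mirrored into whichever
#' tail carries the mass so that extreme truncations (standardised bounds
#' of +-30 and beyond) remain accurate.
#'
#' @param n number of draws (recycling `mean`, `sd`, `lower`, `upper`).
#' @param mean,sd normal location and scale (`sd = 0` returns the clamped
#'   mean).
#' @param lower,upper truncation bounds, `lower < upper`.
#' @return n draws strictly inside `(lower, upper)`.
#' @export
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (any(lower >= upper)) stop("need lower < upper")
  out <- numeric(n)
  degen <- sd <= 0
  if (any(degen))
    out[degen] <- pmin(pmax(mean[degen], lower[degen]), upper[degen])
  i <- which(!degen)
  if (length(i)) {
    a <- (lower[i] - mean[i]) / sd[i]
    b <- (upper[i] - mean[i]) / sd[i]
    mid <- a + b
    flip <- !is.nan(mid) & mid > 0
    a2 <- ifelse(flip, -b, a)
    b2 <- ifelse(flip, -a, b)
    la <- stats::pnorm(a2, log.p = TRUE)
    lb <- stats::pnorm(b2, log.p = TRUE)
    r <- exp(la - lb)
    u <- stats::runif(length(i))
    logp <- lb + log(r + u * (1 - r))
    x <- stats::qnorm(logp, log.p = TRUE)
    x <- ifelse(flip, -x, x)
    val <- mean[i] + sd[i] * x
    eps <- 1e-12 * pmax(1,
                        ifelse(is.finite(lower[i]), abs(lower[i]), 0),
                        ifelse(is.finite(upper[i]), abs(upper[i]), 0))
    val <- ifelse(is.finite(upper[i]), pmin(val, upper[i] - eps), val)
    val <- ifelse(is.finite(lower[i]), pmax(val, lower[i] + eps), val)
    out[i] <- val
  }
  out
}

# fast scalar truncated-normal draw (same log-space inversion as rtnorm,
# without recycling/ifelse overhead); bounds may be infinite
rtnorm1 <- function(mean, sd, lower, upper) {
  if (sd <= 0) return(min(max(mean, lower), upper))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  flip <- !is.nan(a + b) && (a + b) > 0
  if (flip) { tmp <- a; a <- -b; b <- -tmp }
  la <- stats::pnorm(a, log.p = TRUE)
  lb <- stats::pnorm(b, log.p = TRUE)
  r <- exp(la - lb)
  x <- stats::qnorm(lb + log(r + stats::runif(1) * (1 - r)), log.p = TRUE)
  if (flip) x <- -x
  val <- mean + sd * x
  min(max(val, lower + 1e-12), upper - 1e-12)
}

# log-density of the truncated normal (vectorised)
dtnorm <- function(x, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mid <- a + b
  flip <- !is.nan(mid) & mid > 0
  a2 <- ifelse(flip, -b, a)
  b2 <- ifelse(flip, -a, b)
  la <- stats::pnorm(a2, log.p = TRUE)
  lb <- stats::pnorm(b2, log.p = TRUE)
  logz <- lb + log1p(-exp(la - lb))
  ifelse(x <= lower | x >= upper, -Inf,
         stats::dnorm(x, mean, sd, log = TRUE) - logz)
}

# mean of the truncated normal (vectorised); used by mean-mode interpolation
etnorm <- function(mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  out <- pmin(pmax(mean, lower), upper)
  i <- which(sd > 0)
  if (length(i)) {
    a <- (lower - mean)[i] / sd[i]
    b <- (upper - mean)[i] / sd[i]
    z <- stats::pnorm(b) - stats::pnorm(a)
    ok <- z > 1e-14
    adj <- ifelse(ok, (stats::dnorm(a) - stats::dnorm(b)) / pmax(z, 1e-300), 0)
    out[i] <- ifelse(ok, mean[i] + sd[i] * adj, out[i])
  }
  out
}

#' Sample a box-truncated Gaussian-process realisation
#'
#' Draws an n-vector from a zero-mean GP conditioned on every component
#' lying strictly inside `(lower, upper)` -- the prior used for the factor
#' propagation coefficients, truncated to (-1, 1) for stationarity.  For
#' `n = 1` the draw is exact by CDF inversion; otherwise a fixed number of
#' coordinate-wise Gibbs sweeps over univariate truncated-normal full
#' conditionals is run (exact target distribution, no rejection blow-up in
#' high dimension), or rejection sampling can be requested for exact joint
#' draws at small n.
#'
#' @param sites a [spatial_sites()] object.
#' @param hyper a [gp_hyper()] object.
#' @param lower,upper truncation box, `lower < upper`.
#' @param sweeps Gibbs sweeps (default 10).
#' @param init optional starting vector strictly inside the box.
#' @param method `"gibbs"` (default) or `"rejection"` (exact; small n and
#'   moderate variance only).
#' @param kernel correlation kernel.
#' @return an n-vector with all entries strictly inside the box.
#' @export
truncated_gp_sample <- function(sites, hyper, lower = -1, upper = 1,
                                sweeps = 10L, init = NULL,
                                method = c("gibbs", "rejection"),
                                kernel = "exponential") {
  stopifnot(inherits(hyper, "gp_hyper"))
  if (lower >= upper) stop("need lower < upper")
  method <- match.arg(method)
  n <- n_sites(sites)
  mid <- pmin(pmax(0, lower), upper)
  if (hyper$variance == 0) return(rep(mid, n))
  if (n == 1L)
    return(rtnorm(1L, 0, sqrt(hyper$variance), lower, upper))
  sigma <- hyper$variance * correlation_matrix(sites, hyper$range, kernel)
  if (method == "rejection") {
    u <- chol_jitter(sigma)
    for (k in seq_len(100000L)) {
      x <- drop(crossprod(u, stats::rnorm(n)))
      if (all(x > lower & x < upper)) return(x)
    }
    stop("rejection sampling failed; use method = 'gibbs'")
  }
  q <- chol2inv(chol_jitter(sigma))
  x <- if (is.null(init)) rep(mid, n) else init
  csd <- sqrt(1 / diag(q))
  for (s in seq_len(sweeps)) {
    for (j in seq_len(n)) {
      m_j <- -(sum(q[j, ] * x) - q[j, j] * x[j]) / q[j, j]
      x[j] <- rtnorm1(m_j, csd[j], lower, upper)
    }
  }
  x
}

#' Log-spaced candidate grid for a GP range parameter
#'
#' Ten (by default) log-spaced values spanning 5% to 200% of the site-set
#' diameter; used as the discrete support of the range parameters in the
#' Gibbs sampler.
#'
#' @param sites a [spatial_sites()] object (or a positive diameter).
#' @param n grid size.
#' @param span multiplicative span relative to the diameter.
#' @export
range_grid <- function(sites, n = 10L, span = c(0.05, 2)) {
  d <- if (inherits(sites, "spatial_sites")) max(sites$distances) else sites
  if (!is.finite(d) || d <= 0) d <- 1
  exp(seq(log(span[1] * d), log(span[2] * d), length.out = n))
}
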