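# Data structures and probability computations for the multivariate dynamic
# spatial factor model
#   Y_t(s)     = mu_t(s) + Lambda(s) delta_t(s) + eps_t(s)
#   delta_t(s) = Gamma(s) delta_{t-1}(s) + w_t(s)
# with network-specific means and error variances (urban STN vs rural
# IMPROVE monitors) and weekly-averaged log concentrations.

NETWORKS <- c("STN", "IMPROVE")

normalize_network <- function(x) {
  up <- toupper(trimws(as.character(x)))
  up[up %in% c("IMP", "IMPROVE")] <- "IMPROVE"
  bad <- !(up %in% NETWORKS)
  if (any(bad))
    stop("unknown network label(s): ", paste(unique(x[bad]), collapse = ", "))
  up
}

# Monday on or before a date (ISO week anchor)
anchor_monday <- function(d) d - (as.integer(format(d, "%u")) - 1L)

#' Weekly station x pollutant panel
#'
#' The central observed-data container: a `T x n x P` array of weekly mean
#' log concentrations (`NA` = no measurement that week), with the site set,
#' network labels and pollutant names.
#'
#' @param Y `T x n x P` numeric array (log ug/m^3).
#' @param sites a [spatial_sites()] object with `n` sites.
#' @param network length-n vector of `"STN"`/`"IMPROVE"` labels
#'   (case-insensitive).
#' @param pollutant_names length-P character vector.
#' @param anchor optional `Date`: the Monday anchoring week index 1.
#' @return an object of class `pollutant_panel`.
#' @export
pollutant_panel <- function(Y, sites, network, pollutant_names, anchor = NULL) {
  stopifnot(is.array(Y), length(dim(Y)) == 3L)
  d <- dim(Y)
  if (any(d < 1L)) stop("panel dimensions T, n, P must all be >= 1")
  if (d[2] != n_sites(sites)) stop("site dimension mismatch")
  if (length(network) != d[2]) stop("network label length mismatch")
  if (length(pollutant_names) != d[3]) stop("pollutant name length mismatch")
  structure(list(Y = Y, sites = sites, network = normalize_network(network),
                 pollutant_names = as.character(pollutant_names),
                 anchor = anchor),
            class = "pollutant_panel")
}

#' @export
print.pollutant_panel <- function(x, ...) {
  d <- dim(x$Y)
  cat(sprintf(
    "<pollutant_panel> %d weeks x %d sites (%d STN / %d IMPROVE) x %d pollutants; %.1f%% observed\n",
    d[1], d[2], sum(x$network == "STN"), sum(x$network == "IMPROVE"), d[3],
    100 * mean(is.finite(x$Y))))
  invisible(x)
}

panel_dims <- function(panel) {
  d <- dim(panel$Y)
  list(T = d[1], n = d[2], P = d[3])
}

#' Average raw station records into a weekly panel
#'
#' Concentrations are log-transformed and averaged within ISO weeks
#' (Monday-anchored) per site and pollutant; weeks with no measurement stay
#' missing and are excluded from all likelihoods.  Non-positive
#' concentrations cannot be log-transformed and are dropped with a message
#' reporting the count.
#'
#' @param records data.frame with columns `site_id`, `lon`, `lat`,
#'   `network`, `date`, `pollutant`, `value` (concentrations in ug/m^3).
#' @param anchor optional `Date` anchoring week 1; defaults to the Monday on
#'   or before the earliest record.
#' @param pollutants optional character vector fixing pollutant order.
#' @param n_weeks optional panel length (defaults to the last observed week).
#' @param origin optional projection origin passed to [spatial_sites()].
#' @return a [pollutant_panel()].
#' @export
weekly_average <- function(records, anchor = NULL, pollutants = NULL,
                           n_weeks = NULL, origin = NULL) {
  req <- c("site_id", "lon", "lat", "network", "date", "pollutant", "value")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records are missing column(s): ",
                         paste(miss, collapse = ", "))
  dt <- data.table::as.data.table(records)[, req, with = FALSE]
  dt[, date := as.Date(date)]
  dt[, value := as.numeric(value)]
  bad <- !is.finite(dt$value) | dt$value <= 0
  if (any(bad)) {
    message(sum(bad), " record(s) with non-positive or missing concentration dropped")
    dt <- dt[!bad]
  }
  if (nrow(dt) == 0L) stop("no usable records")
  if (is.null(anchor)) anchor <- anchor_monday(min(dt$date))
  dt[, week := as.integer(floor(as.numeric(date - anchor) / 7)) + 1L]
  if (any(dt$week < 1L)) stop("records precede the week anchor")
  if (is.null(n_weeks)) n_weeks <- max(dt$week)
  site_tab <- unique(dt[, .(site_id, lon, lat, network)], by = "site_id")
  sites <- spatial_sites(site_tab$site_id, site_tab$lon, site_tab$lat,
                         origin = origin)
  if (is.null(pollutants)) pollutants <- sort(unique(dt$pollutant))
  unknown <- setdiff(unique(dt$pollutant), pollutants)
  if (length(unknown)) stop("pollutant(s) not in requested set: ",
                            paste(unknown, collapse = ", "))
  dt[, si := match(site_id, site_tab$site_id)]
  dt[, pj := match(pollutant, pollutants)]
  agg <- dt[week <= n_weeks,
            .(m = mean(log(value))), by = .(week, si, pj)]
  Y <- array(NA_real_, dim = c(n_weeks, nrow(site_tab), length(pollutants)))
  Y[cbind(agg$week, agg$si, agg$pj)] <- agg$m
  pollutant_panel(Y, sites, site_tab$network, pollutants, anchor = anchor)
}

#' Network-specific mean structure
#'
#' Pollutant-level intercepts: `mu0[p]` at IMPROVE sites and
#' `mu0[p] + mu1[p]` at STN sites (the STN offset absorbs the systematic
#' urban/rural difference between the two networks).  Optional annual
#' harmonic terms (`amp_cos`, `amp_sin`, period in weeks) add
#' `amp_cos[p] cos(2 pi t / period) + amp_sin[p] sin(2 pi t / period)`.
#'
#' @param mu0 P-vector of IMPROVE-level intercepts (log scale).
#' @param mu1 P-vector of STN offsets.
#' @param amp_cos,amp_sin optional P-vectors of harmonic amplitudes.
#' @param period harmonic period in weeks (annual by default).
#' @export
mean_structure <- function(mu0, mu1, amp_cos = NULL, amp_sin = NULL,
                           period = 52) {
  stopifnot(length(mu0) == length(mu1), all(is.finite(mu0)),
            all(is.finite(mu1)))
  if (!is.null(amp_cos))
    stopifnot(length(amp_cos) == length(mu0), length(amp_sin) == length(mu0))
  structure(list(mu0 = as.numeric(mu0), mu1 = as.numeric(mu1),
                 amp_cos = amp_cos, amp_sin = amp_sin, period = period),
            class = "mean_structure")
}

#' Observation mean for one pollutant at one network
#'
#' @param ms a [mean_structure()].
#' @param network `"STN"` or `"IMPROVE"`.
#' @param p pollutant index.
#' @export
observation_mean <- function(ms, network, p) {
  if (p < 1L || p > length(ms$mu0)) stop("pollutant index out of range")
  net <- normalize_network(network)
  ms$mu0[p] + if (net == "STN") ms$mu1[p] else 0
}

# n x P matrix of time-invariant means; harmonic part handled separately
mean_matrix <- function(ms, network) {
  is_stn <- normalize_network(network) == "STN"
  outer(rep(1, length(network)), ms$mu0) + outer(as.numeric(is_stn), ms$mu1)
}

# T x P matrix of harmonic offsets (zero when no harmonics configured)
harmonic_matrix <- function(ms, n_weeks) {
  if (is.null(ms$amp_cos)) return(NULL)
  tt <- 2 * pi * seq_len(n_weeks) / ms$period
  outer(cos(tt), ms$amp_cos) + outer(sin(tt), ms$amp_sin)
}

#' Network-specific error variances
#'
#' @param sigma2_stn,sigma2_imp P-vectors of positive error variances for
#'   the STN and IMPROVE networks.
#' @export
error_variances <- function(sigma2_stn, sigma2_imp) {
  stopifnot(length(sigma2_stn) == length(sigma2_imp))
  if (any(!is.finite(sigma2_stn)) || any(!is.finite(sigma2_imp)) ||
      any(sigma2_stn <= 0) || any(sigma2_imp <= 0))
    stop("error variances must be positive")
  structure(list(sigma2_stn = as.numeric(sigma2_stn),
                 sigma2_imp = as.numeric(sigma2_imp)),
            class = "error_variances")
}

# n x P matrix of cell variances
variance_matrix <- function(ev, network) {
  is_stn <- normalize_network(network) == "STN"
  out <- outer(as.numeric(is_stn), ev$sigma2_stn) +
    outer(as.numeric(!is_stn), ev$sigma2_imp)
  out
}

#' Assemble a constrained loading array
#'
#' Builds the `n x P x M` loading array `Lambda(s)` from its free fields
#' under the identification scheme: structural zeros above the diagonal
#' (`lambda_pf = 0` for `f > p`), positive diagonal `lambda_pp = exp(g_p)`
#' for `p = 1..M`, and unconstrained sub-diagonal entries.  With `M = 1`
#' every pollutant loads on the single factor.
#'
#' @param log_diag `n x M` matrix of log diagonal fields `g_p(s)`.
#' @param free named list of n-vectors for entries `p > f`, with names
#'   `"p.f"` (e.g. `"3.1"`); missing entries default to zero.
#' @param P,M numbers of pollutants and factors, `M <= P`.
#' @return `n x P x M` array.
#' @export
constrain_loadings <- function(log_diag, free, P, M) {
  if (M > P) stop("number of factors M must not exceed number of pollutants P")
  log_diag <- as.matrix(log_diag)
  n <- nrow(log_diag)
  stopifnot(ncol(log_diag) == M)
  lambda <- array(0, dim = c(n, P, M))
  for (p in seq_len(M)) lambda[, p, p] <- exp(log_diag[, p])
  for (f in seq_len(M)) {
    ps <- if (f < P) seq(f + 1L, P) else integer(0)
    for (p in ps) {
      key <- paste0(p, ".", f)
      if (!is.null(free[[key]])) lambda[, p, f] <- free[[key]]
    }
  }
  lambda
}

# names of the free (sub-diagonal) loading entries for given P, M
free_loading_keys <- function(P, M) {
  keys <- character(0)
  for (f in seq_len(M)) if (f < P)
    keys <- c(keys, paste0(seq(f + 1L, P), ".", f))
  keys
}

#' One step of the factor evolution equation
#'
#' Elementwise `delta_t = gamma * delta_{t-1} + w_t` over sites and factors.
#'
#' @param delta_prev,gamma,innovation `n x M` matrices; `|gamma| < 1`.
#' @export
factor_step <- function(delta_prev, gamma, innovation) {
  if (any(abs(gamma) >= 1)) stop("propagation coefficients must lie in (-1, 1)")
  delta_prev * gamma + innovation
}

# T x n x P fitted mean array given parameters and a factor path
fitted_mean_array <- function(panel, ms, lambda, delta) {
  d <- panel_dims(panel)
  mu <- mean_matrix(ms, panel$network)               # n x P
  M <- dim(lambda)[3]
  fit <- array(rep(mu, each = d$T), dim = c(d$T, d$n, d$P))
  harm <- harmonic_matrix(ms, d$T)                   # T x P or NULL
  if (!is.null(harm))
    fit <- fit + aperm(array(rep(harm, each = d$n),
                             dim = c(d$n, d$T, d$P)), c(2, 1, 3))
  for (m in seq_len(M)) {
    # delta[, , m] is T x n; lambda[, p, m] is n
    del_m <- matrix(delta[, , m], d$T, d$n)
    for (p in seq_len(d$P)) {
      lp <- lambda[, p, m]
      if (any(lp != 0))
        fit[, , p] <- fit[, , p] + sweep(del_m, 2, lp, "*")
    }
  }
  fit
}

#' Gaussian observation log-likelihood of a pollutant panel
#'
#' Sum over non-missing cells of the normal log density of `Y_tp(s)` with
#' mean `mu_tp(s) + [Lambda(s) delta_t(s)]_p` and the network-specific
#' error variance.  Missing cells contribute zero.
#'
#' @param panel a [pollutant_panel()].
#' @param ms a [mean_structure()].
#' @param ev an [error_variances()] object.
#' @param lambda `n x P x M` loading array (see [constrain_loadings()]).
#' @param delta `T x n x M` factor path.
#' @return scalar log-likelihood.
#' @export
pollutant_loglik <- function(panel, ms, ev, lambda, delta) {
  d <- panel_dims(panel)
  stopifnot(all(dim(delta)[1:2] == c(d$T, d$n)), dim(lambda)[1] == d$n,
            dim(lambda)[2] == d$P)
  fit <- fitted_mean_array(panel, ms, lambda, delta)
  sdarr <- array(rep(sqrt(variance_matrix(ev, panel$network)), each = d$T),
                 dim = c(d$T, d$n, d$P))
  obs <- is.finite(panel$Y)
  sum(stats::dnorm(panel$Y[obs], fit[obs], sdarr[obs], log = TRUE))
}

#' Standardize a field to zero mean and unit (population) SD
#'
#' Used for map summaries of estimated pollutant surfaces and factors.
#' Missing entries are ignored and preserved.
#'
#' @param x numeric array or vector.
#' @return same shape, standardized over non-missing entries.
#' @export
standardize_field <- function(x) {
  v <- x[is.finite(x)]
  if (length(v) < 1L) stop("no non-missing values")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (!is.finite(s) || s <= 0) stop("constant field cannot be standardized")
  (x - m) / s
}
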