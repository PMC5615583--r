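# Weekly panel construction and the factor-model probability computations.

make_records <- function(values, dates, site = "s1", pollutant = "Nitrate",
                         lon = -120, lat = 36, network = "STN") {
  data.frame(site_id = site, lon = lon, lat = lat, network = network,
             date = as.Date(dates), pollutant = pollutant, value = values,
             stringsAsFactors = FALSE)
}

test_that("weekly averaging works on the log scale per ISO week", {
  # one record in a week: cell is its log
  r1 <- make_records(exp(2), "2003-01-07")
  p1 <- weekly_average(r1)
  expect_equal(p1$Y[1, 1, 1], 2)
  # two records in the same week average on the log scale
  r2 <- make_records(c(exp(1), exp(3)), c("2003-01-07", "2003-01-09"))
  p2 <- weekly_average(r2)
  expect_equal(p2$Y[1, 1, 1], 2)
  # an empty week stays missing
  r3 <- make_records(c(1, 1), c("2003-01-07", "2003-01-21"))
  p3 <- weekly_average(r3)
  expect_equal(dim(p3$Y)[1], 3)
  expect_true(is.na(p3$Y[2, 1, 1]))
  # non-positive concentrations are dropped with a message
  r4 <- make_records(c(2, -1, 0), rep("2003-01-07", 3))
  expect_message(p4 <- weekly_average(r4), "2 record")
  expect_equal(p4$Y[1, 1, 1], log(2))
})

test_that("observation means follow the network rule", {
  ms <- mean_structure(c(1.2, 0.5), c(0.3, 0.1))
  expect_equal(observation_mean(ms, "IMPROVE", 1), 1.2)
  expect_equal(observation_mean(ms, "STN", 1), 1.5)
  expect_equal(observation_mean(ms, "stn", 2), 0.6)   # case folding
  ms0 <- mean_structure(c(1.2, 0.5), c(0, 0))
  expect_equal(observation_mean(ms0, "STN", 1),
               observation_mean(ms0, "IMPROVE", 1))
  expect_error(observation_mean(ms, "EPA", 1), "network")
  expect_error(observation_mean(ms, "STN", 3), "out of range")
})

test_that("loading constraints give exact zeros, positive diagonal, and the
           right zero count", {
  n <- 3
  lam <- constrain_loadings(matrix(0, n, 2), list(), P = 3, M = 2)
  for (i in 1:n)
    expect_equal(lam[i, , ], cbind(c(1, 0, 0), c(0, 1, 0)))
  # M = 1: all P pollutants load on the single factor
  free <- setNames(lapply(2:9, function(p) rep(0.5, n)), paste0(2:9, ".1"))
  lam9 <- constrain_loadings(matrix(log(2), n, 1), free, P = 9, M = 1)
  expect_equal(lam9[1, 1, 1], 2)
  expect_true(all(lam9[, 2:9, 1] == 0.5))
  # zero count above the diagonal is M(M-1)/2 per site
  set.seed(1)
  lam3 <- constrain_loadings(matrix(rnorm(n * 3), n, 3),
                             list(`2.1` = rnorm(n), `3.1` = rnorm(n),
                                  `3.2` = rnorm(n)), P = 3, M = 3)
  expect_equal(sum(lam3[1, , ] == 0), 3 * (3 - 1) / 2)
  expect_error(constrain_loadings(matrix(0, n, 4), list(), P = 3, M = 4),
               "must not exceed")
})

test_that("factor_step is the elementwise AR recursion", {
  g <- matrix(c(0.5, -0.3), 1)
  expect_equal(factor_step(matrix(c(2, 2), 1), matrix(0, 1, 2),
                           matrix(c(1, 1), 1)),
               matrix(c(1, 1), 1))
  # deterministic recursion: delta_t = gamma^t delta_0
  d <- matrix(c(1, 1), 1)
  for (t in 1:5) d <- factor_step(d, g, matrix(0, 1, 2))
  expect_equal(as.numeric(d), as.numeric(g)^5)
  expect_error(factor_step(d, matrix(c(1, 0.5), 1), d), "\\(-1, 1\\)")
})

test_that("the AR(1) stationary variance matches the long-run sample
           variance", {
  set.seed(31)
  gam <- 0.8; s_w2 <- 1
  n_steps <- 100000
  innov <- rnorm(n_steps, 0, sqrt(s_w2))
  x <- stats::filter(innov, gam, method = "recursive")
  target <- s_w2 / (1 - gam^2)   # 2.778
  expect_equal(target, 1 / 0.36, tolerance = 1e-12)
  # MC standard error of the sample variance with autocorrelation ~ rho
  se <- target * sqrt(2 / n_steps * (1 + gam^2) / (1 - gam^2))
  expect_lt(abs(var(as.numeric(x)) - target), 3 * se * 3)
})

test_that("pollutant_loglik matches a naive loop and handles missingness", {
  set.seed(12)
  n <- 2; T <- 2; P <- 2; M <- 1
  sites <- toy_sites(n)
  Y <- array(rnorm(T * n * P), dim = c(T, n, P))
  Y[1, 2, 1] <- NA
  panel <- pollutant_panel(Y, sites, c("STN", "IMPROVE"), c("a", "b"))
  ms <- mean_structure(c(0.2, -0.1), c(0.3, 0.2))
  ev <- error_variances(c(0.5, 0.8), c(1.1, 0.9))
  lam <- constrain_loadings(matrix(rnorm(n), n, 1),
                            list(`2.1` = rnorm(n)), P, M)
  delta <- array(rnorm(T * n * M), dim = c(T, n, M))
  ll <- pollutant_loglik(panel, ms, ev, lam, delta)
  # naive term-by-term oracle
  ll0 <- 0
  for (t in 1:T) for (s in 1:n) for (p in 1:P) {
    if (!is.finite(Y[t, s, p])) next
    mu <- observation_mean(ms, panel$network[s], p) +
      sum(lam[s, p, ] * delta[t, s, ])
    v <- if (panel$network[s] == "STN") ev$sigma2_stn[p] else ev$sigma2_imp[p]
    ll0 <- ll0 + dnorm(Y[t, s, p], mu, sqrt(v), log = TRUE)
  }
  expect_equal(ll, ll0, tolerance = 1e-12)
  # single standard-normal cell at its mean
  p1 <- pollutant_panel(array(0, dim = c(1, 1, 1)),
                        spatial_sites_xy("a", 0, 0), "STN", "x")
  ll1 <- pollutant_loglik(p1, mean_structure(0, 0), error_variances(1, 1),
                          array(0, dim = c(1, 1, 1)),
                          array(0, dim = c(1, 1, 1)))
  expect_equal(ll1, -0.5 * log(2 * pi), tolerance = 1e-12)
  # an all-missing panel contributes zero
  pna <- pollutant_panel(array(NA_real_, dim = c(1, 1, 1)),
                         spatial_sites_xy("a", 0, 0), "STN", "x")
  expect_equal(pollutant_loglik(pna, mean_structure(0, 0),
                                error_variances(1, 1),
                                array(0, dim = c(1, 1, 1)),
                                array(0, dim = c(1, 1, 1))), 0)
})

test_that("pollutant_loglik is invariant to simultaneous site permutation", {
  set.seed(14)
  n <- 4; T <- 3; P <- 2; M <- 1
  x <- runif(n, 0, 100); y <- runif(n, 0, 100)
  Y <- array(rnorm(T * n * P), dim = c(T, n, P))
  net <- c("STN", "IMPROVE", "STN", "IMPROVE")
  ms <- mean_structure(c(0, 0.5), c(0.2, 0.1))
  ev <- error_variances(c(1, 0.7), c(0.9, 1.2))
  ld <- matrix(rnorm(n), n, 1); fr <- list(`2.1` = rnorm(n))
  delta <- array(rnorm(T * n * M), dim = c(T, n, M))
  ll1 <- pollutant_loglik(
    pollutant_panel(Y, spatial_sites_xy(1:n, x, y), net, c("a", "b")),
    ms, ev, constrain_loadings(ld, fr, P, M), delta)
  perm <- c(3, 1, 4, 2)
  ll2 <- pollutant_loglik(
    pollutant_panel(Y[, perm, , drop = FALSE],
                    spatial_sites_xy(1:n, x[perm], y[perm]),
                    net[perm], c("a", "b")),
    ms, ev,
    constrain_loadings(ld[perm, , drop = FALSE],
                       list(`2.1` = fr$`2.1`[perm]), P, M),
    delta[, perm, , drop = FALSE])
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("the log-likelihood at the truth beats perturbed parameters on
           average", {
  set.seed(15)
  wins <- 0
  for (rep in 1:20) {
    st <- generate_stations(8, 5, seed = rep)
    tr <- make_truth("toy")
    sim <- suppressMessages(generate_pollution(st, tr, T_weeks = 15,
                                               seed = 100 + rep))
    truth <- sim$truth
    lam <- constrain_loadings(truth$fields$log_diag, truth$fields$free,
                              truth$P, truth$M)
    ms <- mean_structure(truth$mu0, truth$mu1)
    ev <- error_variances(truth$sigma2_stn, truth$sigma2_imp)
    ll_true <- pollutant_loglik(sim$panel, ms, ev, lam, truth$delta)
    ms_bad <- mean_structure(truth$mu0 + 0.5, truth$mu1)
    ll_bad <- pollutant_loglik(sim$panel, ms_bad, ev, lam, truth$delta)
    if (ll_true > ll_bad) wins <- wins + 1
  }
  expect_gte(wins, 15)
})

test_that("implied cross-pollutant covariance is Lambda V Lambda' + diag", {
  set.seed(16)
  n <- 1; P <- 3; M <- 1
  lam <- constrain_loadings(matrix(log(1.3), 1, 1),
                            list(`2.1` = 0.9, `3.1` = 0.4), P, M)
  L <- matrix(lam[1, , ], P, M)
  v_delta <- 1.7
  sig2 <- c(0.3, 0.5, 0.4)
  target <- tcrossprod(L) * v_delta + diag(sig2)
  draws <- matrix(rnorm(50000 * M, 0, sqrt(v_delta)), ncol = M) %*% t(L) +
    matrix(rnorm(50000 * P), ncol = P) %*% diag(sqrt(sig2))
  emp <- cov(draws)
  expect_lt(max(abs(emp - target)), 0.05)
})

test_that("standardize_field uses the population-SD convention", {
  expect_equal(standardize_field(c(1, 2, 3)),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  z <- standardize_field(rnorm(50, 5, 2))
  expect_equal(standardize_field(z), z, tolerance = 1e-12)   # idempotent
  x <- rnorm(30)
  expect_equal(standardize_field(3 * x - 7), standardize_field(x),
               tolerance = 1e-12)                            # affine invariant
  expect_error(standardize_field(rep(2, 5)), "constant")
  # missing entries preserved
  y <- c(1, NA, 3)
  out <- standardize_field(y)
  expect_true(is.na(out[2]))
})
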