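# Full-conditional updates: conjugacy algebra and distributional checks
# against closed forms.

test_that("error-variance update follows IG conjugacy", {
  # k = 10, SS = 10, prior IG(2, 1) -> posterior IG(7, 6), mean 6/(7-1) = 1
  sites <- toy_sites(1)
  Y <- array(0, dim = c(10, 1, 1))
  panel <- pollutant_panel(Y, sites, "STN", "x")
  fit <- array(-1, dim = c(10, 1, 1))       # residuals all 1, SS = 10
  set.seed(40)
  draws <- replicate(20000, update_error_variances(panel, fit)$sigma2_stn[1])
  expect_equal(mean(draws), 1, tolerance = 0.03)
  # KS against the analytic inverse-gamma CDF
  ig_cdf <- function(q) pgamma(1 / q, shape = 7, rate = 6,
                               lower.tail = FALSE)
  ks <- suppressWarnings(ks.test(draws, ig_cdf))
  expect_lt(ks$statistic, 0.02)
  # an empty group draws from the prior (IMPROVE side has no sites here)
  prior_draws <- replicate(5000,
                           update_error_variances(panel, fit)$sigma2_imp[1])
  ks2 <- suppressWarnings(ks.test(prior_draws, function(q)
    pgamma(1 / q, shape = 2, rate = 1, lower.tail = FALSE)))
  expect_lt(ks2$statistic, 0.03)
})

test_that("mean-offset update is the normal-normal posterior", {
  # one observation, unit variances, prior N(0, 100):
  # posterior mean = y * 100 / 101
  sites <- spatial_sites_xy("a", 0, 0)
  y <- 2.5
  panel <- pollutant_panel(array(y, dim = c(1, 1, 1)), sites, "IMPROVE", "x")
  ms <- mean_structure(0, 0)
  ev <- error_variances(1, 1)
  set.seed(41)
  draws <- replicate(20000,
                     update_mean_offsets(panel, ms, ev,
                                         array(0, dim = c(1, 1, 1)))$mu0[1])
  expect_equal(mean(draws), y * 100 / 101, tolerance = 0.02)
  # posterior precision = prior precision + sum 1/sigma2
  expect_equal(var(draws), 1 / (1 / 100 + 1), tolerance = 0.03)
  # KS against the exact posterior normal
  ks <- suppressWarnings(
    ks.test(draws, function(q) pnorm(q, y * 100 / 101,
                                     sqrt(1 / (1 / 100 + 1)))))
  expect_lt(ks$statistic, 0.02)
})

test_that("with no data the mean-offset update draws from the prior", {
  sites <- spatial_sites_xy("a", 0, 0)
  panel <- pollutant_panel(array(NA_real_, dim = c(1, 1, 1)), sites,
                           "IMPROVE", "x")
  set.seed(42)
  draws <- replicate(5000,
                     update_mean_offsets(panel, mean_structure(0, 0),
                                         error_variances(1, 1),
                                         array(0, dim = c(1, 1, 1)))$mu0[1])
  expect_equal(sd(draws), 10, tolerance = 0.3)
  expect_lt(abs(mean(draws)), 0.5)
})

test_that("free-loading update recovers the least-squares slope under a
           flat prior", {
  # single site, M = 1: with a huge prior variance the posterior mean of
  # the free loading is the regression slope of the residual on delta
  set.seed(43)
  n <- 1; T <- 60; P <- 2; M <- 1
  sites <- spatial_sites_xy("a", 0, 0)
  delta <- array(rnorm(T), dim = c(T, 1, 1))
  lam_true <- 0.8
  Y <- array(0, dim = c(T, 1, P))
  Y[, 1, 1] <- exp(0) * delta[, 1, 1] + rnorm(T, 0, 0.3)
  Y[, 1, 2] <- lam_true * delta[, 1, 1] + rnorm(T, 0, 0.3)
  panel <- pollutant_panel(Y, sites, "STN", c("a", "b"))
  ms <- mean_structure(c(0, 0), c(0, 0))
  ev <- error_variances(c(0.09, 0.09), c(0.09, 0.09))
  lf <- list(log_diag = matrix(0, 1, 1), free = list(`2.1` = 0), P = P, M = M)
  hyp <- list(`2.1` = list(s2 = 1e8, chol = matrix(1, 1, 1)),
              `d.1` = list(s2 = 1e-12, chol = matrix(1, 1, 1)))
  set.seed(44)
  draws <- replicate(3000, update_loadings(panel, ms, ev, lf, delta,
                                           hyp)$free[["2.1"]])
  slope <- sum(delta[, 1, 1] * Y[, 1, 2]) / sum(delta[, 1, 1]^2)
  expect_equal(mean(draws), slope, tolerance = 0.01)
  # zero-variance GP prior pins loadings at 0 (free) / 1 (diagonal)
  hyp0 <- list(`2.1` = list(s2 = 1e-14, chol = matrix(1, 1, 1)),
               `d.1` = list(s2 = 1e-14, chol = matrix(1, 1, 1)))
  lf0 <- update_loadings(panel, ms, ev, lf, delta, hyp0)
  expect_lt(abs(lf0$free[["2.1"]]), 1e-3)
  expect_lt(abs(exp(lf0$log_diag[1, 1]) - 1), 1e-3)
  # structural zeros preserved exactly
  lam <- constrain_loadings(lf0$log_diag, lf0$free, P, M)
  expect_identical(lam[1, 1, 1] > 0, TRUE)
})

test_that("propagation update matches AR(1) conjugacy under a flat prior
           and stays in (-1, 1)", {
  set.seed(45)
  T <- 80
  gam_true <- 0.6
  delta0 <- matrix(0.5, 1, 1)
  delta <- array(0, dim = c(T, 1, 1))
  prev <- 0.5
  for (t in 1:T) delta[t, 1, 1] <- prev <- gam_true * prev + rnorm(1, 0, 0.8)
  prior_kinv <- list(matrix(1e-10, 1, 1))    # flat
  q_innov <- matrix(1 / 0.64, 1, 1)
  draws <- replicate(4000,
                     update_propagation(delta0, delta, matrix(0, 1, 1),
                                        prior_kinv, q_innov, sweeps = 2)[1, 1])
  dprev <- c(delta0[1, 1], delta[-T, 1, 1])
  ls <- sum(dprev * delta[, 1, 1]) / sum(dprev^2)
  expect_equal(mean(draws), ls, tolerance = 0.02)
  expect_true(all(draws > -1 & draws < 1))
  # strongly informative delta_1 = delta_0 pushes mass near +1, never past
  dd <- array(rep(2, 2), dim = c(2, 1, 1))
  d0 <- matrix(2, 1, 1)
  d2 <- replicate(500, update_propagation(d0, dd, matrix(0, 1, 1),
                                          list(matrix(1e-6, 1, 1)),
                                          matrix(1e4, 1, 1),
                                          sweeps = 3)[1, 1])
  expect_true(all(d2 < 1))
  expect_gt(mean(d2), 0.9)
})

test_that("probit latent utilities respect signs and the half-normal
           moment", {
  set.seed(46)
  n <- 50000
  y <- cbind(rep(1L, n), rep(0L, n))
  eta <- matrix(0, n, 2)
  z <- matrix(c(0.5, -0.5), n, 2, byrow = TRUE)
  z <- update_probit_latents(y, eta, diag(2), z)
  expect_true(all(z[, 1] > 0) && all(z[, 2] < 0))
  # E[z | z > 0] = sqrt(2/pi) for a standard half-normal
  expect_equal(mean(z[, 1]), sqrt(2 / pi), tolerance = 0.01)
  # rho = 0 equals independent truncated normals
  ks <- suppressWarnings(ks.test(z[, 1], function(q)
    pmax(2 * pnorm(q) - 1, 0)))
  expect_lt(ks$statistic, 0.02)
  # correlated case keeps signs for mixed outcomes
  om <- matrix(c(1, 0.6, 0.6, 1), 2)
  y2 <- cbind(rbinom(2000, 1, 0.5), rbinom(2000, 1, 0.5))
  z2 <- matrix(ifelse(y2 == 1, 0.5, -0.5), 2000, 2)
  for (k in 1:3) z2 <- update_probit_latents(y2, matrix(0, 2000, 2), om, z2)
  expect_true(all(sign(z2) == ifelse(y2 == 1, 1, -1)))
})

test_that("beta/weekly joint draw matches brute-force Gaussian algebra on a
           toy and draws from the prior with no subjects", {
  set.seed(47)
  # q = 2, no exposure columns, Omega = I: posterior precision I + X'X
  X <- matrix(rnorm(40), 20, 2)
  z <- matrix(rnorm(40), 20, 2)
  w_kinv <- matrix(0, 0, 0)
  D <- matrix(0, 20, 0)
  S <- 20000
  draws <- matrix(NA, S, 2)
  for (s in 1:S) {
    bw <- update_beta_weekly(X, D, z, diag(2), w_kinv)
    draws[s, ] <- bw$beta[, 1]
  }
  A <- diag(2) + crossprod(X)
  mean_post <- solve(A, crossprod(X, z[, 1]))
  expect_lt(max(abs(colMeans(draws) - as.numeric(mean_post))), 0.01)
  expect_lt(max(abs(unname(cov(draws)) - unname(solve(A)))), 0.01)
  # no subjects: prior draw N(0, I) for beta, GP prior for w
  kw <- dsfm:::weekly_prior_kinv(1, 2)
  pd <- replicate(8000, update_beta_weekly(matrix(0, 0, 2),
                                           matrix(0, 0, 6),
                                           matrix(0, 0, 2), diag(2),
                                           kw)$wmat[1, 1])
  expect_equal(sd(pd), 1, tolerance = 0.05)
})

test_that("omega update is the conjugate inverse Wishart", {
  set.seed(48)
  # N = 0: prior IW(I2, 2); E[Omega^{-1}] = 2 I
  oinv <- matrix(0, 2, 2)
  S <- 20000
  for (s in 1:S) oinv <- oinv + solve(update_omega(matrix(0, 0, 2))) / S
  expect_equal(oinv, 2 * diag(2), tolerance = 0.1)
  # draws are SPD
  ok <- replicate(200, {
    om <- update_omega(matrix(rnorm(20), 10, 2))
    all(eigen(om, symmetric = TRUE, only.values = TRUE)$values > 0)
  })
  expect_true(all(ok))
  # conjugacy: with residuals, E[Omega^{-1}] = (nu + N) (Psi + S)^{-1}
  resid <- matrix(rnorm(400, 0, 1.5), 200, 2)
  psi <- diag(2) + crossprod(resid)
  oinv2 <- matrix(0, 2, 2)
  for (s in 1:S) oinv2 <- oinv2 + solve(update_omega(resid)) / S
  expect_equal(oinv2, (2 + 200) * solve(psi), tolerance = 0.05)
})

test_that("GP variance update is conjugate and the range grid normalizes
           and recovers the truth", {
  set.seed(49)
  # IG(2,1) with quad Q and count k -> IG(2 + k/2, 1 + Q/2)
  draws <- replicate(20000, update_gp_variance(12, 10))
  ig_cdf <- function(q) pgamma(1 / q, shape = 7, rate = 7,
                               lower.tail = FALSE)
  ks <- suppressWarnings(ks.test(draws, ig_cdf))
  expect_lt(ks$statistic, 0.02)
  # grid weights normalize
  sites <- toy_sites(8)
  grid <- range_grid(sites, 6)
  chols <- lapply(grid, function(p) chol(correlation_matrix(sites, p)))
  idx <- update_gp_range(rnorm(8), 1, chols)
  expect_equal(sum(attr(idx, "weights")), 1, tolerance = 1e-12)
  # range recovery: fields simulated at a grid value have their posterior
  # mode within one grid step in most replicates
  set.seed(50)
  big <- spatial_sites_xy(1:30, runif(30, 0, 300), runif(30, 0, 300))
  grid2 <- range_grid(big, 10)
  target <- which.min(abs(grid2 - 50))
  chols2 <- lapply(grid2, function(p) chol(correlation_matrix(big, p)))
  hits <- 0
  for (r in 1:50) {
    f <- vapply(1:4, function(i)
      gp_sample(big, gp_hyper(1, grid2[target])), numeric(30))
    w <- attr(update_gp_range(f, 1, chols2), "weights")
    if (abs(which.max(w) - target) <= 1) hits <- hits + 1
  }
  expect_gte(hits, 40)
})
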