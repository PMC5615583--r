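# Gaussian-process primitives: kernels, sampling, kriging, truncation.

test_that("correlation matrix has the exponential closed form and is PSD", {
  sites <- toy_sites(4)
  R <- correlation_matrix(sites, 2)
  expect_equal(diag(R), rep(1, 4))
  expect_equal(R, t(R))
  d12 <- sites$distances[1, 2]
  expect_equal(R[1, 2], exp(-d12 / 2))
  # at distance equal to the range the correlation is exp(-1)
  s2 <- spatial_sites_xy(c("a", "b"), c(0, 7), c(0, 0))
  expect_equal(correlation_matrix(s2, 7)[1, 2], exp(-1), tolerance = 1e-12)
  # eigendecomposition oracle: random layout, phi = 1
  ev <- eigen(correlation_matrix(toy_sites(6), 1), symmetric = TRUE)$values
  expect_true(min(ev) >= -1e-10)
  expect_error(correlation_matrix(sites, -1), "positive")
  expect_error(correlation_matrix(sites, 0), "positive")
})

test_that("correlation matrix is permutation-equivariant", {
  set.seed(7)
  n <- 6
  x <- runif(n, 0, 100); y <- runif(n, 0, 100)
  perm <- sample(n)
  R1 <- correlation_matrix(spatial_sites_xy(1:n, x, y), 50)
  R2 <- correlation_matrix(spatial_sites_xy(1:n, x[perm], y[perm]), 50)
  expect_equal(R2, R1[perm, perm], tolerance = 1e-12)
})

test_that("gp_sample is degenerate at zero variance and seed-reproducible", {
  sites <- toy_sites(5)
  mu <- c(1, 2, 3, 4, 5)
  expect_identical(gp_sample(sites, gp_hyper(0, 10), mean = mu), mu)
  set.seed(11); a <- gp_sample(sites, gp_hyper(2, 80))
  set.seed(11); b <- gp_sample(sites, gp_hyper(2, 80))
  expect_identical(a, b)
})

test_that("gp_sample at n = 1 reproduces the standard normal variance", {
  s1 <- spatial_sites_xy("a", 0, 0)
  set.seed(42)
  draws <- replicate(10000, gp_sample(s1, gp_hyper(1, 5)))
  # MC check within 3 standard errors of the sampling variance
  se <- sqrt(2 / (10000 - 1))
  expect_lt(abs(var(draws) - 1), 3 * se)
  expect_lt(abs(mean(draws)), 3 / sqrt(10000))
})

test_that("kriging interpolates exactly and reverts to the prior", {
  obs <- toy_sites(4)
  set.seed(3)
  vals <- rnorm(4)
  hyper <- gp_hyper(1.5, 60)
  # coincident site: mean = observed value, variance ~ 0
  at_obs <- spatial_sites_xy("new", obs$coords[2, 1], obs$coords[2, 2])
  kr <- krige_conditional(obs, vals, at_obs, hyper, nugget = 0)
  expect_equal(kr$mean, vals[2], tolerance = 1e-5)
  expect_lt(abs(kr$cov[1, 1]), 1e-5)
  # far site: mean -> 0, variance -> prior variance
  far <- spatial_sites_xy("far", 1e5, 1e5)
  kr2 <- krige_conditional(obs, vals, far, hyper)
  expect_lt(abs(kr2$mean), 1e-8)
  expect_equal(kr2$cov[1, 1], hyper$variance, tolerance = 1e-6)
})

test_that("kriging matches direct conditioning of the joint Gaussian", {
  obs <- toy_sites(2)
  new <- spatial_sites_xy("t", 120, 40)
  hyper <- gp_hyper(2, 90)
  set.seed(5)
  vals <- rnorm(2)
  kr <- krige_conditional(obs, vals, new, hyper)
  # brute force on the 3x3 joint covariance
  all3 <- spatial_sites_xy(c("a", "b", "t"),
                           c(obs$coords[, 1], 120), c(obs$coords[, 2], 40))
  S <- hyper$variance * correlation_matrix(all3, hyper$range)
  mu_c <- S[3, 1:2] %*% solve(S[1:2, 1:2], vals)
  v_c <- S[3, 3] - S[3, 1:2] %*% solve(S[1:2, 1:2], S[1:2, 3])
  expect_equal(kr$mean, as.numeric(mu_c), tolerance = 1e-6)
  expect_equal(kr$cov[1, 1], as.numeric(v_c), tolerance = 1e-6)
})

test_that("kriging variance never exceeds the prior variance and the tower
           property holds", {
  set.seed(9)
  obs <- toy_sites(5)
  vals <- rnorm(5)
  hyper <- gp_hyper(1.2, 70)
  targets <- spatial_sites_xy(c("t1", "t2"), c(30, 220), c(150, 10))
  kr <- krige_conditional(obs, vals, targets, hyper)
  expect_true(all(diag(kr$cov) <= hyper$variance + 1e-8))
  # tower property: condition on obs, then a mid set A, equals direct
  amid <- spatial_sites_xy("a1", 100, 100)
  # direct joint conditional of (A, targets) given obs
  coords <- rbind(amid$coords, targets$coords)
  allu <- spatial_sites_xy(c("a1", "t1", "t2"), coords[, 1], coords[, 2])
  kru <- krige_conditional(obs, vals, allu, hyper)
  # sequential: t | obs, A  averaged over A | obs must equal t | obs
  # (checked on the mean by plugging the conditional mean of A)
  kra <- krige_conditional(obs, vals, amid, hyper)
  # build conditional of targets given obs and A at A's conditional mean:
  # E[t | obs] = E_A[E[t | obs, A]] -- linearity makes the plug-in exact
  obs6 <- spatial_sites_xy(c(obs$ids, "a1"),
                           c(obs$coords[, 1], 100), c(obs$coords[, 2], 100))
  krt <- krige_conditional(obs6, c(vals, kra$mean), targets, hyper)
  expect_equal(krt$mean, kru$mean[2:3], tolerance = 1e-8)
})

test_that("kriging errors on conflicting duplicate sites with zero nugget", {
  obs <- spatial_sites_xy(c("a", "a2"), c(0, 0), c(0, 0))
  new <- spatial_sites_xy("t", 10, 10)
  expect_error(
    krige_conditional(obs, c(0, 1), new, gp_hyper(1, 10), nugget = 0),
    "ill-conditioned")
  # consistent duplicates or a nugget are fine
  expect_silent(krige_conditional(obs, c(1, 1), new, gp_hyper(1, 10)))
  expect_silent(krige_conditional(obs, c(0, 1), new, gp_hyper(1, 10),
                                  nugget = 0.5))
})

test_that("rtnorm respects bounds, matches the truncated-normal CDF, and
           survives extreme truncation", {
  set.seed(21)
  x <- rtnorm(20000, 0.3, 1.2, -1, 1)
  expect_true(all(x > -1 & x < 1))
  # Kolmogorov-Smirnov against the analytic truncated CDF
  a <- (-1 - 0.3) / 1.2; b <- (1 - 0.3) / 1.2
  cdf <- function(q) (pnorm((q - 0.3) / 1.2) - pnorm(a)) / (pnorm(b) - pnorm(a))
  ks <- suppressWarnings(ks.test(x, cdf))
  expect_gt(ks$p.value, 1e-4)
  # extreme one-sided truncation stays finite and in-bounds
  y <- rtnorm(1000, -30, 1, lower = 0, upper = Inf)
  expect_true(all(is.finite(y) & y >= 0))
  z <- rtnorm(1000, 25, 1, lower = -Inf, upper = 0)
  expect_true(all(is.finite(z) & z <= 0))
  expect_identical(rtnorm(3, 5, 0, -1, 1), rep(1, 3))  # sd = 0 clamps
})

test_that("truncated GP sampling obeys the box and the n = 1 law", {
  sites <- toy_sites(10)
  hyper <- gp_hyper(0.8, 100)
  set.seed(2)
  x <- truncated_gp_sample(sites, hyper)
  expect_true(all(x > -1 & x < 1))
  expect_identical(truncated_gp_sample(sites, gp_hyper(0, 10)), rep(0, 10))
  # n = 1: empirical CDF against the analytic truncated normal
  s1 <- spatial_sites_xy("a", 0, 0)
  set.seed(4)
  draws <- replicate(50000, truncated_gp_sample(s1, gp_hyper(1, 5)))
  z <- pnorm(1) - pnorm(-1)
  grid <- seq(-0.99, 0.99, length.out = 199)
  emp <- ecdf(draws)(grid)
  ana <- (pnorm(grid) - pnorm(-1)) / z
  expect_lt(max(abs(emp - ana)), 0.01)
})

test_that("rejection-sampled and Gibbs-sampled truncated GPs agree in law", {
  sites <- toy_sites(3)
  hyper <- gp_hyper(0.4, 120)
  set.seed(8)
  a <- replicate(4000, truncated_gp_sample(sites, hyper,
                                           method = "rejection")[1])
  b <- replicate(4000, truncated_gp_sample(sites, hyper, sweeps = 20)[1])
  expect_lt(abs(mean(a) - mean(b)), 4 * sqrt(var(a) / 4000 + var(b) / 4000))
  expect_lt(abs(sd(a) - sd(b)) / sd(a), 0.1)
})

test_that("range grid spans the requested fractions of the diameter", {
  sites <- toy_sites(5)
  g <- range_grid(sites, n = 10)
  D <- max(sites$distances)
  expect_equal(length(g), 10)
  expect_equal(g[1], 0.05 * D, tolerance = 1e-12)
  expect_equal(g[10], 2 * D, tolerance = 1e-12)
})
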