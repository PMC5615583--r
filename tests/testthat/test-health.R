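# Bivariate probit model pieces: design coding, latent means, orthant
# probabilities, exposure extraction.

raw_cohort_row <- function(id = "A1", palate = 0, lip = 0, age = "25_29",
                           edu = "hs", sex = "F", hbp = 0, pre = 0,
                           smoke = 0, alc = 0,
                           conception = "2003-02-03",
                           lon = -120, lat = 36) {
  row <- data.frame(id = id, cleft_palate = palate, cleft_lip = lip,
                    age_cat = age, edu_cat = edu, fetal_sex = sex,
                    hbp = hbp, prediabetes = pre, smoke = smoke,
                    alcohol = alc, conception_date = conception,
                    stringsAsFactors = FALSE)
  for (w in 3:8) {
    row[[paste0("lon_w", w)]] <- lon
    row[[paste0("lat_w", w)]] <- lat
  }
  row
}

test_that("build_design dummy-codes with the documented reference levels", {
  raw <- rbind(raw_cohort_row("A1", age = 22, edu = "less_hs", sex = "M"),
               raw_cohort_row("A2", age = "35_plus", edu = "college",
                              sex = "F", smoke = 1))
  co <- build_design(raw)
  # numeric age 22 maps to the 20-24 contrast
  expect_equal(unname(co$x[1, "age_20_24"]), 1L)
  expect_equal(sum(co$x[1, ]), 1L)   # only the age indicator fires
  # reference-level subject has an all-zero row
  ref <- build_design(raw_cohort_row("R", age = "19_under",
                                     edu = "less_hs", sex = "M"))
  expect_true(all(ref$x == 0))
  # schema: N rows in, N out, 12 fixed columns
  expect_equal(dim(co$x), c(2L, 12L))
  expect_identical(colnames(co$x), dsfm:::COVARIATE_NAMES)
  expect_error(build_design(raw_cohort_row(age = "unknown_cat")),
               "age category")
  expect_error(build_design(rbind(raw_cohort_row("D"), raw_cohort_row("D"))),
               "duplicate")
  bad <- raw_cohort_row("M1")
  bad$lat_w5 <- NA
  expect_error(build_design(bad), "M1")
})

test_that("latent_mean combines covariate and weekly exposure terms", {
  q <- 1
  expect_equal(latent_mean(matrix(0, q, 2), array(0, dim = c(6, 1, 2)),
                           1, matrix(0, 6, 1)), c(0, 0))
  expect_equal(latent_mean(matrix(c(0.5, -0.5), 1, 2),
                           array(0, dim = c(6, 1, 2)), 1, matrix(0, 6, 1)),
               c(0.5, -0.5))
  # M = 1, unit weekly coefficients, exposures 1..6 -> 21 per defect
  w <- array(1, dim = c(6, 1, 2))
  expect_equal(latent_mean(matrix(0, 1, 2), w, 0, matrix(1:6, 6, 1)),
               c(21, 21))
})

test_that("defect_probability is the probit link", {
  expect_equal(defect_probability(0), 0.5)
  expect_equal(defect_probability(1.959964), 0.975, tolerance = 1e-6)
  eta <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(defect_probability(eta)) > 0))
  expect_error(defect_probability(NA), "finite")
})

test_that("pbvnorm matches the numerical-integration oracle including
           strong correlation", {
  cases <- expand.grid(h = c(-2.5, -0.7, 0, 1.1, 2.2),
                       k = c(-1.8, 0, 0.4, 2.6),
                       rho = c(-0.999, -0.95, -0.5, 0, 0.3, 0.8, 0.99, 0.999))
  for (i in seq_len(nrow(cases))) {
    p <- pbvnorm(cases$h[i], cases$k[i], cases$rho[i])
    expect_equal(p, pbvnorm_oracle(cases$h[i], cases$k[i], cases$rho[i]),
                 tolerance = 1e-8,
                 label = paste("case", i))
  }
  # degenerate limits
  expect_equal(pbvnorm(0.5, 1.5, 1), pnorm(0.5))
  expect_equal(pbvnorm(0.5, -0.2, -1), pnorm(0.5) + pnorm(-0.2) - 1)
})

test_that("joint outcome probabilities: independence, closed-form orthant,
           and normalization", {
  # independent halves
  expect_equal(joint_outcome_logprob(c(0, 0), diag(2), c(1, 1)), log(0.25),
               tolerance = 1e-9)
  # orthant closed form 1/4 + asin(rho)/(2 pi)
  rho <- 0.51
  om <- matrix(c(1, rho, rho, 1), 2)
  expect_equal(exp(joint_outcome_logprob(c(0, 0), om, c(1, 1))),
               0.25 + asin(rho) / (2 * pi), tolerance = 1e-9)
  expect_equal(exp(joint_outcome_logprob(c(0, 0), om, c(1, 1))), 0.33517,
               tolerance = 1e-4)
  # four outcome patterns sum to one for random (eta, omega)
  set.seed(30)
  for (i in 1:100) {
    eta <- rnorm(2, 0, 1.5)
    a <- matrix(rnorm(4), 2); om <- crossprod(a) + diag(0.2, 2)
    tot <- sum(vapply(list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
                      function(y) exp(joint_outcome_logprob(eta, om, y)),
                      numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
  expect_error(joint_outcome_logprob(c(0, 0),
                                     matrix(c(1, 1, 1, 1), 2), c(1, 1)),
               "rho")
})

test_that("with identity covariance the joint probability factorizes", {
  set.seed(33)
  for (i in 1:25) {
    eta <- rnorm(2, 0, 2)
    y <- rbinom(2, 1, 0.5)
    lp <- joint_outcome_logprob(eta, diag(2), y)
    lp_f <- sum(pnorm((2 * y - 1) * eta, log.p = TRUE))
    expect_equal(lp, lp_f, tolerance = 1e-9)
  }
})

test_that("exposure extraction uses the week-specific residence and errors
           outside the panel span", {
  ms <- micro_study(seed = 5)
  panel <- ms$sim$panel
  truth <- ms$truth
  d0h <- list(gp_hyper(truth$s_d2[1], truth$phi_d[1]))
  ih <- gp_hyper(truth$s_w2, truth$phi_w)
  gh <- gp_hyper(truth$gamma_s2, truth$gamma_phi)
  # mother living exactly at station 1: mean-mode exposure equals that
  # station's factor path at her gestation weeks
  lonlat <- panel$sites$lonlat[1, ]
  raw <- raw_cohort_row("S1", lon = lonlat[1], lat = lonlat[2],
                        conception = as.character(panel$anchor))
  co1 <- build_design(raw)
  expo <- extract_exposures(co1, panel, truth$delta0, truth$delta,
                            truth$fields$gamma, ih, d0h, gh, mode = "mean")
  cweek <- 1   # gestational week l occupies panel week cweek + l - 1
  expect_equal(as.numeric(expo[1, , 1]),
               truth$delta[cweek + 3:8 - 1, 1, 1], tolerance = 1e-6)
  # mover: weeks 3-5 at address A, 6-8 at address B
  raw2 <- raw_cohort_row("M1", conception = as.character(panel$anchor))
  for (w in 6:8) { raw2[[paste0("lon_w", w)]] <- -118
                   raw2[[paste0("lat_w", w)]] <- 33.5 }
  co2 <- build_design(raw2)
  loc <- dsfm:::exposure_locations(co2, panel)
  expect_equal(loc$loc_idx[1, ], c(1, 1, 1, 2, 2, 2))
  # conception date too late: gestational weeks fall off the panel
  raw3 <- raw_cohort_row("L1", conception = as.character(panel$anchor + 300))
  co3 <- build_design(raw3)
  expect_error(extract_exposures(co3, panel, truth$delta0, truth$delta,
                                 truth$fields$gamma, ih, d0h, gh),
               "L1")
})
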