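# Synthetic monitoring-network and cohort generator.  Emulates the study
# conditions the analysis assumes: ~40 stations with ~20 in a denser study
# subregion, urban-biased STN labels, 9 (or a reduced set of) pollutants
# measured every 3-6 days over multiple years with seasonality and strong
# cross-pollutant correlation induced by shared latent factors, one
# pollutant withheld from the IMPROVE network, and a case-control cohort
# with correlated cleft outcomes and ~15% residential movers.  The
# generated truth is returned (and serializable) for parameter-recovery
# testing.

# California-like geographic boxes (degrees); abstract, no real geography
DOMAIN_BOX <- list(lon = c(-124, -115), lat = c(32.5, 42))
STUDY_BOX <- list(lon = c(-121.5, -118.5), lat = c(35, 38.5))
MOVER_BOXES <- list(
  list(lon = c(-123.3, -121.8), lat = c(36.8, 38.8)),   # northern coastal
  list(lon = c(-118.4, -116.5), lat = c(32.8, 34.3)))   # southern coastal

runif_box <- function(n, box) {
  cbind(lon = stats::runif(n, box$lon[1], box$lon[2]),
        lat = stats::runif(n, box$lat[1], box$lat[2]))
}

in_box <- function(lon, lat, box) {
  lon >= box$lon[1] & lon <= box$lon[2] & lat >= box$lat[1] & lat <= box$lat[2]
}

#' Generate monitoring-station locations and network labels
#'
#' Random station layout over a rectangular domain with `n_study` stations
#' inside a denser study subregion; STN (urban) labels are drawn with
#' higher probability inside the study subregion, IMPROVE (rural)
#' elsewhere, and at least one station of each network is guaranteed.
#'
#' @param n_total,n_study station counts (`n_study <= n_total`).
#' @param seed optional RNG seed.
#' @param p_stn_study,p_stn_outside STN probability inside/outside the
#'   study box.
#' @return list with `sites` (a [spatial_sites()]), `network`, and
#'   `in_study` logical.
#' @export
generate_stations <- function(n_total = 40, n_study = 20, seed = NULL,
                              p_stn_study = 0.75, p_stn_outside = 0.25) {
  if (n_study > n_total) stop("n_study must not exceed n_total")
  if (!is.null(seed)) set.seed(seed)
  inside <- runif_box(n_study, STUDY_BOX)
  n_out <- n_total - n_study
  outside <- matrix(numeric(0), 0, 2)
  while (nrow(outside) < n_out) {
    cand <- runif_box(max(2 * (n_out - nrow(outside)), 4), DOMAIN_BOX)
    keep <- !in_box(cand[, 1], cand[, 2], STUDY_BOX)
    outside <- rbind(outside, cand[keep, , drop = FALSE])
  }
  outside <- outside[seq_len(n_out), , drop = FALSE]
  xy <- rbind(inside, outside)
  in_study <- rep(c(TRUE, FALSE), c(n_study, n_out))
  p <- ifelse(in_study, p_stn_study, p_stn_outside)
  network <- ifelse(stats::runif(n_total) < p, "STN", "IMPROVE")
  if (n_total >= 2) {
    if (!any(network == "STN")) network[1] <- "STN"
    if (!any(network == "IMPROVE")) network[n_total] <- "IMPROVE"
  }
  sites <- spatial_sites(sprintf("S%02d", seq_len(n_total)),
                         xy[, 1], xy[, 2])
  list(sites = sites, network = network, in_study = in_study)
}

SPECIATED_POLLUTANTS <- c("Ammonium", "Nitrate", "Sulfate", "Total Carbon Mass",
                      "Calcium", "Iron", "Potassium", "Silicon", "Sulfur")

#' Generative truth parameters
#'
#' Assembles the scalar/vector truth for the generator.  The `"toy"`
#' preset (P = 4 pollutants, M = 1 factor) is the fast test configuration;
#' `"study_scale"` mirrors the 9-pollutant speciated-PM2.5 list with two
#' near-duplicate loading pairs (ammonium/nitrate, sulfate/sulfur) that
#' reproduce the strong observed cross-pollutant correlations, annual
#' seasonal harmonics, and ammonium withheld from IMPROVE sites.
#'
#' @param preset `"toy"` or `"study_scale"`.
#' @param M number of latent factors.
#' @param beta_scale multiplier on the covariate effects (use > 1 for
#'   strong-signal classification experiments).
#' @param w_scale multiplier on the weekly exposure effects.
#' @return an object of class `truth_bundle` (parameters only; site fields
#'   and latent paths are attached by the generators).
#' @export
make_truth <- function(preset = c("toy", "study_scale"), M = 1,
                       beta_scale = 1, w_scale = 1) {
  preset <- match.arg(preset)
  if (preset == "toy") {
    P <- 4
    pollutants <- c("Nitrate", "Sulfate", "Total Carbon Mass", "Sulfur")
    mu0 <- c(0.7, 0.4, 1.2, -0.3)
    lambda_base <- c(1.0, 0.7, 0.5, 0.68)
    amp_cos <- NULL; amp_sin <- NULL
    stn_only <- "Nitrate"
  } else {
    P <- 9
    pollutants <- SPECIATED_POLLUTANTS
    mu0 <- c(0.0, 0.7, 0.4, 1.2, -1.2, -1.6, -2.0, -1.4, -0.3)
    # ammonium/nitrate and sulfate/sulfur rows are near-duplicates with
    # small error variance, reproducing the strong observed correlations
    lambda_base <- c(1.30, 1.26, 1.00, 0.50, 0.18, 0.25, 0.30, 0.20, 0.98)
    amp_cos <- c(0.45, 0.5, 0.25, 0.35, 0.15, 0.15, 0.1, 0.2, 0.25)
    amp_sin <- rep(0.1, 9)
    stn_only <- "Ammonium"
  }
  lb <- matrix(0, P, M)
  lb[, 1] <- lambda_base
  if (M > 1) for (m in 2:M) lb[seq(m, P), m] <- 0.3 * (-1)^m
  # covariate effects (palate, lip) at reported-study magnitudes
  beta_palate <- c(0.345, 0.439, 0.440, 0.385, 0.023, -0.109, -0.430,
                   -0.247, 0.050, 1.214, 0.183, 0.106)
  beta_lip <- c(0.540, 0.556, 0.605, 0.232, -0.021, 0.032, -0.480,
                -0.405, 0.332, 1.175, 0.089, 0.049)
  w_palate <- c(0.20, -0.25, -0.10, 0.40, -0.15, -0.10)
  w_lip <- c(0.10, -0.15, -0.05, 0.25, -0.10, -0.05)
  wmat <- matrix(0, 6 * M, 2)
  wmat[1:6, 1] <- w_palate * w_scale
  wmat[1:6, 2] <- w_lip * w_scale
  if (M > 1) for (m in 2:M) {
    wmat[(m - 1) * 6 + 1:6, ] <- 0    # extra factors carry no health effect
  }
  structure(list(
    version = "dsfm-truth-1",
    preset = preset, P = P, M = M,
    pollutant_names = pollutants,
    stn_only = stn_only,
    mu0 = mu0, mu1 = rep(0.3, P),
    sigma2_stn = if (P == 9)
      c(0.05, 0.05, 0.04, 0.20, 0.25, 0.25, 0.25, 0.25, 0.04)
      else rep(0.15, P),
    sigma2_imp = if (P == 9)
      c(0.08, 0.08, 0.06, 0.25, 0.30, 0.30, 0.30, 0.30, 0.06)
      else rep(0.20, P),
    amp_cos = amp_cos, amp_sin = amp_sin, period = 52,
    s_w2 = 0.6, phi_w = 200, s_d2 = rep(1, M), phi_d = rep(250, M),
    gamma_base = 0.6, gamma_wiggle_sd = 0.15, gamma_phi = 400,
    gamma_s2 = 0.25,
    lambda_base = lb, log_diag_sd = 0.05, lambda_wiggle_sd = 0.12,
    lambda_phi = 300,
    beta = matrix(c(beta_palate, beta_lip), ncol = 2) * beta_scale,
    w = wmat, omega = matrix(c(1, 0.51, 0.51, 1), 2, 2),
    covariate_freqs = list(
      age = c(0.09, 0.26, 0.30, 0.21, 0.14),
      edu = c(0.25, 0.30, 0.25, 0.20),
      female = 0.49, hbp = 0.10, prediabetes = 0.05,
      smoke = 0.17, alcohol = 0.25)),
    class = "truth_bundle")
}

# site-level truth fields (loadings, propagation) for a station layout
truth_site_fields <- function(truth, sites) {
  n <- n_sites(sites); M <- truth$M; P <- truth$P
  log_diag <- vapply(seq_len(M), function(m)
    gp_sample(sites, gp_hyper(truth$log_diag_sd^2, truth$lambda_phi)),
    numeric(n))
  log_diag <- matrix(log_diag, n, M) +
    matrix(log(pmax(diag(truth$lambda_base[seq_len(M), , drop = FALSE]),
                    1e-6)), n, M, byrow = TRUE)
  free <- list()
  for (key in free_loading_keys(P, M)) {
    pf <- as.integer(strsplit(key, ".", fixed = TRUE)[[1]])
    free[[key]] <- truth$lambda_base[pf[1], pf[2]] +
      gp_sample(sites, gp_hyper(truth$lambda_wiggle_sd^2, truth$lambda_phi))
  }
  gamma <- vapply(seq_len(M), function(m) {
    g <- truth$gamma_base +
      gp_sample(sites, gp_hyper(truth$gamma_wiggle_sd^2, truth$gamma_phi))
    pmin(pmax(g, -0.95), 0.95)
  }, numeric(n))
  list(log_diag = log_diag, free = free, gamma = matrix(gamma, n, M))
}

#' Simulate pollutant measurements and the weekly panel
#'
#' Simulates the latent factor paths and weekly observations from the
#' factor model at the given stations, thins them to a 3-6 day sampling
#' cadence per site with occasional whole-week outages, withholds the
#' designated STN-only pollutant from IMPROVE sites, and returns both the
#' raw measurement records and the weekly-averaged panel (the panel is
#' recomputed from the records, so weekly averaging round-trips by
#' construction).
#'
#' @param stations result of [generate_stations()].
#' @param truth a [make_truth()] bundle.
#' @param T_weeks number of weeks to simulate.
#' @param seed optional RNG seed.
#' @param start_date first Monday of week 1.
#' @param cadence integer vector of candidate between-visit gaps in days.
#' @param outage_prob per-site probability that a week has no visit.
#' @param seasonal include the truth's harmonic seasonal means (if any).
#' @return list with `records` (data.frame), `panel`
#'   ([pollutant_panel()]), and `truth` (input bundle extended with the
#'   site fields, latent paths and the noiseless weekly field).
#' @export
generate_pollution <- function(stations, truth, T_weeks = 104, seed = NULL,
                               start_date = as.Date("2003-01-06"),
                               cadence = 3:6, outage_prob = 0.1,
                               seasonal = !is.null(truth$amp_cos)) {
  if (!is.null(seed)) set.seed(seed)
  sites <- stations$sites; network <- stations$network
  n <- n_sites(sites); P <- truth$P; M <- truth$M
  fields <- truth_site_fields(truth, sites)
  lambda <- constrain_loadings(fields$log_diag, fields$free, P, M)
  delta0 <- vapply(seq_len(M), function(m)
    gp_sample(sites, gp_hyper(truth$s_d2[m], truth$phi_d[m])), numeric(n))
  delta0 <- matrix(delta0, n, M)
  delta <- array(0, dim = c(T_weeks, n, M))
  innov_hyper <- gp_hyper(truth$s_w2, truth$phi_w)
  prev <- delta0
  for (t in seq_len(T_weeks)) {
    innov <- vapply(seq_len(M), function(m) gp_sample(sites, innov_hyper),
                    numeric(n))
    prev <- factor_step(prev, fields$gamma, matrix(innov, n, M))
    delta[t, , ] <- prev
  }
  ms <- mean_structure(truth$mu0, truth$mu1,
                       amp_cos = if (seasonal) truth$amp_cos else NULL,
                       amp_sin = if (seasonal) truth$amp_sin else NULL,
                       period = truth$period)
  panel_shell <- pollutant_panel(array(0, dim = c(T_weeks, n, P)), sites,
                                 network, truth$pollutant_names,
                                 anchor = start_date)
  ywk <- fitted_mean_array(panel_shell, ms, lambda, delta)
  sdm <- sqrt(variance_matrix(error_variances(truth$sigma2_stn,
                                              truth$sigma2_imp), network))
  noise <- array(stats::rnorm(T_weeks * n * P), dim = c(T_weeks, n, P)) *
    array(rep(sdm, each = T_weeks), dim = c(T_weeks, n, P))
  ywk_obs <- ywk + noise
  stn_only_idx <- match(truth$stn_only, truth$pollutant_names)
  stn_only_idx <- stn_only_idx[!is.na(stn_only_idx)]
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    days <- cumsum(c(sample(0:2, 1),
                     sample(cadence, ceiling(7 * T_weeks / min(cadence)),
                            replace = TRUE)))
    days <- days[days < 7 * T_weeks]
    wk <- days %/% 7 + 1L
    keep_wk <- stats::runif(T_weeks) >= outage_prob
    sel <- keep_wk[wk]
    days <- days[sel]; wk <- wk[sel]
    if (!length(days)) next
    pset <- seq_len(P)
    if (network[i] == "IMPROVE" && length(stn_only_idx))
      pset <- setdiff(pset, stn_only_idx)
    recs[[i]] <- data.frame(
      site_id = sites$ids[i],
      lon = unname(sites$lonlat[i, 1]), lat = unname(sites$lonlat[i, 2]),
      network = network[i],
      date = start_date + rep(days, length(pset)),
      pollutant = rep(truth$pollutant_names[pset], each = length(days)),
      value = exp(as.numeric(ywk_obs[cbind(rep(wk, length(pset)), i,
                                           rep(pset, each = length(wk)))])),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  panel <- weekly_average(records, anchor = start_date,
                          pollutants = truth$pollutant_names,
                          n_weeks = T_weeks)
  truth$fields <- fields
  truth$delta0 <- delta0
  truth$delta <- delta
  truth$seasonal <- seasonal
  list(records = records, panel = panel, truth = truth)
}

sample_cat <- function(n, levels, probs) {
  levels[sample.int(length(levels), n, replace = TRUE, prob = probs)]
}

#' Simulate a case-control cohort linked to the pollutant field
#'
#' Draws prospective subjects (Table-1-like covariate frequencies,
#' residences in the study subregion, `mover_fraction` relocating once
#' mid-window to a distant high-density subregion), evaluates their true
#' exposures from the simulated factor field via its conditional law at
#' the residence locations, generates correlated latent utilities
#' `Z ~ N(eta, Omega)` and outcomes by their signs, and oversamples until
#' the requested case/control counts are reached (cases are subjects with
#' either defect).
#'
#' @param sim result of [generate_pollution()] (records/panel/truth).
#' @param n_cases,n_controls target counts for case-control sampling.
#' @param n_subjects if non-`NULL`, draw this many subjects prospectively
#'   (no outcome-dependent selection) and ignore the case/control targets;
#'   used by the parameter-recovery studies, where selection on outcome
#'   would tilt the estimand of the uncorrected probit.
#' @param mover_fraction probability a subject moves during the window.
#' @param seed optional RNG seed.
#' @param max_batches oversampling cap; if reached, a warning is issued
#'   and the achieved counts are returned.
#' @return list with `cohort` (a [cohort_table()]), `exposures`
#'   (`N x 6 x M` truth), `z` (`N x 2` latent utilities), and `raw`
#'   (data.frame in the cohort file schema).
#' @export
generate_cohort <- function(sim, n_cases = 208, n_controls = 358,
                            n_subjects = NULL, mover_fraction = 0.15,
                            seed = NULL, max_batches = 60L) {
  prospective <- !is.null(n_subjects)
  if (prospective) { n_cases <- n_subjects; n_controls <- 0L }
  if (!is.null(seed)) set.seed(seed)
  truth <- sim$truth; panel <- sim$panel
  tt <- panel_dims(panel)$T; M <- truth$M
  q <- nrow(truth$beta)
  batch <- max(200L, ceiling((n_cases + n_controls) / 2))
  got <- list()
  counts <- c(cases = 0L, controls = 0L)
  serial <- 0L
  for (b in seq_len(max_batches)) {
    n <- batch
    fr <- truth$covariate_freqs
    age <- sample_cat(n, AGE_LEVELS, fr$age)
    edu <- sample_cat(n, EDU_LEVELS, fr$edu)
    sex <- ifelse(stats::runif(n) < fr$female, "F", "M")
    hbp <- as.integer(stats::runif(n) < fr$hbp)
    pre <- as.integer(stats::runif(n) < fr$prediabetes)
    smk <- as.integer(stats::runif(n) < fr$smoke)
    alc <- as.integer(stats::runif(n) < fr$alcohol)
    cweek <- sample.int(tt - 7L, n, replace = TRUE)
    cdate <- panel$anchor + (cweek - 1L) * 7L + sample.int(7L, n, TRUE) - 1L
    home <- runif_box(n, STUDY_BOX)
    mover <- stats::runif(n) < mover_fraction
    move_week <- sample(4:8, n, replace = TRUE)   # gestational week of move
    far <- runif_box(n, MOVER_BOXES[[1]])
    south <- stats::runif(n) < 0.5
    far[south, ] <- runif_box(sum(south), MOVER_BOXES[[2]])
    res <- array(0, dim = c(n, 6, 2))
    for (l in seq_along(GESTATION_WEEKS)) {
      use_far <- mover & GESTATION_WEEKS[l] >= move_week
      res[, l, 1] <- ifelse(use_far, far[, 1], home[, 1])
      res[, l, 2] <- ifelse(use_far, far[, 2], home[, 2])
    }
    serial_ids <- sprintf("C%05d", serial + seq_len(n))
    serial <- serial + n
    raw <- data.frame(id = serial_ids, cleft_palate = 0L, cleft_lip = 0L,
                      age_cat = age, edu_cat = edu, fetal_sex = sex,
                      hbp = hbp, prediabetes = pre, smoke = smk,
                      alcohol = alc, conception_date = cdate,
                      stringsAsFactors = FALSE)
    for (l in seq_along(GESTATION_WEEKS)) {
      raw[[paste0("lon_w", GESTATION_WEEKS[l])]] <- res[, l, 1]
      raw[[paste0("lat_w", GESTATION_WEEKS[l])]] <- res[, l, 2]
    }
    cohort_b <- cohort_table(serial_ids, matrix(0L, n, 2),
                             build_design_matrix(age, edu, sex, hbp, pre,
                                                 smk, alc),
                             res, cdate)
    expo <- extract_exposures(
      cohort_b, panel, truth$delta0, truth$delta, truth$fields$gamma,
      gp_hyper(truth$s_w2, truth$phi_w),
      lapply(seq_len(M), function(m)
        gp_hyper(truth$s_d2[m], truth$phi_d[m])),
      gp_hyper(truth$gamma_s2, truth$gamma_phi), mode = "sample")
    D <- matrix(expo, n, 6 * M)
    eta <- latent_mean_matrix(truth$beta, truth$w, cohort_b$x, D)
    u <- chol(truth$omega)
    z <- eta + matrix(stats::rnorm(2 * n), n, 2) %*% u
    y <- (z > 0) + 0L
    is_case <- rowSums(y) > 0
    if (prospective) {
      need <- n_cases - counts["cases"]
      take <- seq_len(min(n, need))
      take_case <- take; take_ctrl <- integer(0)
    } else {
      need_cases <- n_cases - counts["cases"]
      need_ctrl <- n_controls - counts["controls"]
      take_case <- which(is_case)[seq_len(min(sum(is_case), need_cases))]
      take_ctrl <- which(!is_case)[seq_len(min(sum(!is_case), need_ctrl))]
      take <- sort(c(take_case, take_ctrl))
    }
    if (length(take)) {
      raw$cleft_palate <- y[, 1]; raw$cleft_lip <- y[, 2]
      got[[length(got) + 1L]] <- list(
        raw = raw[take, , drop = FALSE],
        res = res[take, , , drop = FALSE],
        expo = expo[take, , , drop = FALSE],
        z = z[take, , drop = FALSE])
      counts["cases"] <- counts["cases"] + length(take_case)
      counts["controls"] <- counts["controls"] + length(take_ctrl)
    }
    if (counts["cases"] >= n_cases && counts["controls"] >= n_controls) break
  }
  if (counts["cases"] < n_cases || counts["controls"] < n_controls)
    warning(sprintf("oversampling cap reached: %d cases / %d controls achieved",
                    counts["cases"], counts["controls"]))
  raw <- do.call(rbind, lapply(got, `[[`, "raw"))
  rownames(raw) <- NULL
  res <- do.call(abind1, lapply(got, `[[`, "res"))
  expo <- do.call(abind1, lapply(got, `[[`, "expo"))
  z <- do.call(rbind, lapply(got, `[[`, "z"))
  cohort <- build_design(raw)
  list(cohort = cohort, exposures = expo, z = z, raw = raw)
}

# bind 3-d arrays along the first margin
abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, dim = c(sum(vapply(parts, function(a) dim(a)[1],
                                     numeric(1))), d[2], d[3]))
  at <- 0L
  for (a in parts) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

build_design_matrix <- function(age, edu, sex, hbp, pre, smk, alc) {
  cbind(age_20_24 = as.integer(age == "20_24"),
        age_25_29 = as.integer(age == "25_29"),
        age_30_34 = as.integer(age == "30_34"),
        age_35_plus = as.integer(age == "35_plus"),
        edu_hs = as.integer(edu == "hs"),
        edu_some_college = as.integer(edu == "some_college"),
        edu_college = as.integer(edu == "college"),
        female = as.integer(sex == "F"),
        hbp = hbp, prediabetes = pre, smoke = smk, alcohol = alc)
}

# ---- truth serialization ---------------------------------------------------

encode_val <- function(v) {
  if (is.array(v) || is.matrix(v))
    list(`.array` = TRUE, dim = dim(v), data = as.numeric(v))
  else if (is.list(v)) lapply(v, encode_val)
  else v
}

decode_val <- function(v) {
  if (is.list(v)) {
    if (isTRUE(v$.array))
      array(as.numeric(unlist(v$data)), dim = as.integer(unlist(v$dim)))
    else lapply(v, decode_val)
  } else v
}

#' Save / load a truth bundle
#'
#' Lossless JSON round-trip of all generative parameters, site fields and
#' latent paths, with a schema-version stamp.
#'
#' @param truth a `truth_bundle`.
#' @param path file path.
#' @export
save_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_bundle"))
  jsonlite::write_json(lapply(unclass(truth), encode_val), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_truth
#' @export
load_truth <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(raw$version, "dsfm-truth-1"))
    stop("unsupported truth schema version: ", raw$version %||% "<missing>")
  out <- lapply(raw, decode_val)
  # scalars/vectors arrive as lists of length-1 elements; flatten
  out <- lapply(out, function(v) {
    if (is.list(v) && length(v) && all(vapply(v, function(x)
      is.atomic(x) && length(x) == 1L, logical(1)))) unlist(v) else v
  })
  class(out) <- "truth_bundle"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
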