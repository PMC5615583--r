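# Bivariate probit model for cleft palate and cleft lip with individual
# covariates and weekly latent-factor exposures over gestational weeks 3-8:
#   Z_i = beta' x_i + sum_m sum_{l=3}^{8} w_{lm} delta_{ilm} + eps_i,
#   eps_i ~ N(0, Omega),   Y~_ij = I(Z_ij > 0).

GESTATION_WEEKS <- 3:8

AGE_LEVELS <- c("19_under", "20_24", "25_29", "30_34", "35_plus")
EDU_LEVELS <- c("less_hs", "hs", "some_college", "college")

COVARIATE_NAMES <- c(
  "age_20_24", "age_25_29", "age_30_34", "age_35_plus",
  "edu_hs", "edu_some_college", "edu_college",
  "female", "hbp", "prediabetes", "smoke", "alcohol")

#' Covariate contrast labels in reporting style
#'
#' Long labels used by [summarize_fit()] for the covariate rows, e.g.
#' `"Maternal age 20-24 vs. 19 and under"`.
#' @export
covariate_labels <- function() {
  c("Maternal age 20-24 vs. 19 and under",
    "Maternal age 25-29 vs. 19 and under",
    "Maternal age 30-34 vs. 19 and under",
    "Maternal age 35+ vs. 19 and under",
    "High school diploma vs. Less than high school",
    "Some college vs. Less than high school",
    "College graduate vs. Less than high school",
    "Fetus Sex-Female", "High Blood Pressure", "Maternal Prediabetes",
    "Maternal Smoking", "Maternal Alcohol Use")
}

normalize_age <- function(x, id) {
  num <- suppressWarnings(as.numeric(as.character(x)))
  out <- ifelse(!is.na(num),
                as.character(cut(num, breaks = c(-Inf, 19, 24, 29, 34, Inf),
                                 labels = AGE_LEVELS)),
                NA_character_)
  if (!anyNA(out)) return(out)
  x <- ifelse(is.na(out), as.character(x), out)
  v <- gsub("[^a-z0-9]+", "_", tolower(trimws(as.character(x))))
  v[v %in% c("19_and_under", "under_19", "_19", "le19")] <- "19_under"
  v[v %in% c("35_", "35_and_older", "35_plus", "35_over", "35")] <- "35_plus"
  bad <- !(v %in% AGE_LEVELS)
  if (any(bad))
    stop("unknown maternal age category for subject(s): ",
         paste(id[bad], collapse = ", "))
  v
}

normalize_edu <- function(x, id) {
  v <- gsub("[^a-z0-9]+", "_", tolower(trimws(as.character(x))))
  v[v %in% c("less_than_high_school", "less_hs", "lt_hs")] <- "less_hs"
  v[v %in% c("high_school", "hs", "high_school_diploma")] <- "hs"
  v[v %in% c("some_college", "somecollege")] <- "some_college"
  v[v %in% c("college", "college_graduate", "college_degree")] <- "college"
  bad <- !(v %in% EDU_LEVELS)
  if (any(bad))
    stop("unknown maternal education category for subject(s): ",
         paste(id[bad], collapse = ", "))
  v
}

normalize_binary <- function(x, what, id) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(v))
  out[v %in% c("1", "yes", "y", "true")] <- 1L
  out[v %in% c("0", "no", "n", "false")] <- 0L
  if (anyNA(out))
    stop("unknown ", what, " value for subject(s): ",
         paste(id[is.na(out)], collapse = ", "))
  out
}

#' Build the cohort design from raw records
#'
#' Dummy-codes the maternal covariates with the reference levels used in
#' the reporting convention: age "19 and under", education "less than high
#' school", male fetus, and absence of high blood pressure, prediabetes,
#' smoking and alcohol use.  A reference-level subject therefore has an
#' all-zero covariate row (the probit model has no intercept; the baseline
#' defect probability at zero exposure is 0.5 on the latent scale).
#'
#' @param raw data.frame with columns `id`, `cleft_palate`, `cleft_lip`,
#'   `age_cat` (category label or numeric age), `edu_cat`, `fetal_sex`
#'   (`"M"`/`"F"`), `hbp`, `prediabetes`, `smoke`, `alcohol` (0/1 or
#'   yes/no), `conception_date`, and residence coordinates `lon_w3`,
#'   `lat_w3`, ..., `lon_w8`, `lat_w8` for gestational weeks 3-8.
#' @return an object of class `cohort_table` with fields `ids`, `y`
#'   (N x 2: palate, lip), `x` (N x 12 design), `residences`
#'   (N x 6 x 2 lon/lat), `conception_date`.
#' @export
build_design <- function(raw) {
  req <- c("id", "cleft_palate", "cleft_lip", "age_cat", "edu_cat",
           "fetal_sex", "hbp", "prediabetes", "smoke", "alcohol",
           "conception_date",
           paste0(rep(c("lon_w", "lat_w"), 6), rep(GESTATION_WEEKS, each = 2)))
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("cohort records are missing column(s): ",
                         paste(miss, collapse = ", "))
  id <- as.character(raw$id)
  if (anyDuplicated(id)) stop("duplicate subject id(s): ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  n <- length(id)
  age <- normalize_age(raw$age_cat, id)
  edu <- normalize_edu(raw$edu_cat, id)
  sex <- toupper(substr(trimws(as.character(raw$fetal_sex)), 1, 1))
  if (!all(sex %in% c("M", "F")))
    stop("unknown fetal sex for subject(s): ",
         paste(id[!(sex %in% c("M", "F"))], collapse = ", "))
  x <- cbind(
    age_20_24 = as.integer(age == "20_24"),
    age_25_29 = as.integer(age == "25_29"),
    age_30_34 = as.integer(age == "30_34"),
    age_35_plus = as.integer(age == "35_plus"),
    edu_hs = as.integer(edu == "hs"),
    edu_some_college = as.integer(edu == "some_college"),
    edu_college = as.integer(edu == "college"),
    female = as.integer(sex == "F"),
    hbp = normalize_binary(raw$hbp, "high blood pressure", id),
    prediabetes = normalize_binary(raw$prediabetes, "prediabetes", id),
    smoke = normalize_binary(raw$smoke, "smoking", id),
    alcohol = normalize_binary(raw$alcohol, "alcohol", id))
  y <- cbind(palate = normalize_binary(raw$cleft_palate, "cleft palate", id),
             lip = normalize_binary(raw$cleft_lip, "cleft lip", id))
  res <- array(NA_real_, dim = c(n, 6, 2),
               dimnames = list(NULL, paste0("w", GESTATION_WEEKS),
                               c("lon", "lat")))
  for (j in seq_along(GESTATION_WEEKS)) {
    res[, j, 1] <- as.numeric(raw[[paste0("lon_w", GESTATION_WEEKS[j])]])
    res[, j, 2] <- as.numeric(raw[[paste0("lat_w", GESTATION_WEEKS[j])]])
  }
  if (any(!is.finite(res))) {
    bad <- unique(id[rowSums(!is.finite(res)) > 0])
    stop("missing residence coordinate(s) for subject(s): ",
         paste(bad, collapse = ", "))
  }
  cohort_table(id, y, x, res, as.Date(raw$conception_date))
}

#' Cohort container
#'
#' Low-level constructor used by [build_design()] and the synthetic-data
#' generator; validates outcome coding and dimensions.
#'
#' @param ids subject identifiers.
#' @param y N x 2 binary outcomes (cleft palate, cleft lip).
#' @param x N x q 0/1 design matrix.
#' @param residences N x 6 x 2 lon/lat residence history for gestational
#'   weeks 3-8.
#' @param conception_date length-N `Date` vector.
#' @export
cohort_table <- function(ids, y, x, residences, conception_date) {
  y <- as.matrix(y); x <- as.matrix(x)
  n <- length(ids)
  stopifnot(nrow(y) == n, ncol(y) == 2L, nrow(x) == n,
            all(dim(residences)[1:2] == c(n, 6L)),
            length(conception_date) == n)
  if (!all(y %in% c(0, 1))) stop("outcomes must be binary 0/1")
  structure(list(ids = as.character(ids), y = y, x = x,
                 residences = residences,
                 conception_date = conception_date),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects (%d palate, %d lip cases), %d covariates\n",
              length(x$ids), sum(x$y[, 1]), sum(x$y[, 2]), ncol(x$x)))
  invisible(x)
}

# N x 6 matrix of panel week indices for gestational weeks 3..8; errors if
# any fall outside 1..T, listing the offending subjects.
gestation_week_index <- function(cohort, panel) {
  if (is.null(panel$anchor))
    stop("panel has no week anchor; cannot place conception dates")
  cweek <- as.integer(floor(as.numeric(
    anchor_monday(cohort$conception_date) - panel$anchor) / 7)) + 1L
  idx <- outer(cweek, GESTATION_WEEKS - 1L, "+")
  tt <- panel_dims(panel)$T
  bad <- rowSums(idx < 1L | idx > tt) > 0
  if (any(bad))
    stop("gestational weeks outside the pollutant panel span for subject(s): ",
         paste(cohort$ids[bad], collapse = ", "))
  idx
}

#' Latent probit mean for one subject
#'
#' `eta_j = x' beta_j + sum_m sum_l w_{lmj} delta_{ilm}` for each defect j.
#'
#' @param beta `q x 2` coefficient matrix.
#' @param w `6 x M x 2` weekly exposure coefficients.
#' @param x_i covariate q-vector.
#' @param delta_i `6 x M` exposure matrix for gestational weeks 3-8.
#' @return length-2 vector (palate, lip).
#' @export
latent_mean <- function(beta, w, x_i, delta_i) {
  beta <- as.matrix(beta)
  delta_i <- as.matrix(delta_i)
  stopifnot(length(x_i) == nrow(beta), nrow(delta_i) == 6L)
  wm <- array(w, dim = c(6L, ncol(delta_i), 2L))
  expo <- vapply(1:2, function(j) sum(wm[, , j] * delta_i), numeric(1))
  drop(crossprod(beta, x_i)) + expo
}

# vectorised latent means: X (N x q), D (N x 6M), beta (q x 2), wmat (6M x 2)
latent_mean_matrix <- function(beta, wmat, X, D) {
  X %*% beta + D %*% wmat
}

#' Marginal defect probability
#'
#' `Phi(eta)` on the unit-variance (reporting) scale.
#'
#' @param eta linear predictor.
#' @export
defect_probability <- function(eta) {
  stopifnot(all(is.finite(eta)))
  stats::pnorm(eta)
}

#' Joint log-probability of a bivariate binary outcome
#'
#' `log P(sign(Z) matches y)` for `Z ~ N(eta, omega)`, computed as a
#' bivariate-normal rectangle probability.  Cleft lip and cleft palate can
#' co-occur; the four sign patterns partition probability one.
#'
#' @param eta length-2 latent mean.
#' @param omega 2 x 2 SPD covariance of the latent utilities.
#' @param y length-2 binary outcome.
#' @return scalar log-probability.
#' @export
joint_outcome_logprob <- function(eta, omega, y) {
  s <- 2 * y - 1
  sd1 <- sqrt(omega[1, 1]); sd2 <- sqrt(omega[2, 2])
  rho <- omega[1, 2] / (sd1 * sd2)
  if (!is.finite(rho) || abs(rho) >= 1)
    stop("latent correlation must satisfy |rho| < 1")
  p <- pbvnorm(s[1] * eta[1] / sd1, s[2] * eta[2] / sd2, s[1] * s[2] * rho)
  log(max(p, 1e-300))
}

# vectorised over subjects: eta N x 2, y N x 2, scalar omega
outcome_logprob_matrix <- function(eta, omega, y) {
  sd1 <- sqrt(omega[1, 1]); sd2 <- sqrt(omega[2, 2])
  rho <- omega[1, 2] / (sd1 * sd2)
  if (!is.finite(rho) || abs(rho) >= 1)
    stop("latent correlation must satisfy |rho| < 1")
  s1 <- 2 * y[, 1] - 1
  s2 <- 2 * y[, 2] - 1
  out <- numeric(nrow(eta))
  for (pat in list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    i <- which(s1 == pat[1] & s2 == pat[2])
    if (length(i))
      out[i] <- log(pmax(pbvnorm(pat[1] * eta[i, 1] / sd1,
                                 pat[2] * eta[i, 2] / sd2,
                                 pat[1] * pat[2] * rho), 1e-300))
  }
  out
}
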