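# Readers and writers for the delimited-text interfaces: station
# measurement files, cohort files, posterior draw directories (one
# plain-text file per parameter block plus a JSON manifest), and posterior
# summary tables.

STATION_COLUMNS <- c("site_id", "lon", "lat", "network", "date",
                     "pollutant", "value")

#' Read a station measurement file
#'
#' Delimited text with header
#' `site_id,lon,lat,network,date,pollutant,value`; dates ISO-8601; network
#' labels case-insensitive (`stn` / `improve` / `imp`).  Rows with
#' unparseable dates or values are rejected and counted in a message.
#'
#' @param path file path.
#' @return data.frame of typed records.
#' @export
read_station_file <- function(path) {
  if (!file.exists(path)) stop("station file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(character = "site_id"))
  miss <- setdiff(STATION_COLUMNS, names(dt))
  if (length(miss))
    stop("station file is missing column(s): ", paste(miss, collapse = ", "))
  dt <- as.data.frame(dt)[, STATION_COLUMNS]
  dt$date <- as.Date(as.character(dt$date), format = "%Y-%m-%d")
  dt$value <- suppressWarnings(as.numeric(dt$value))
  dt$lon <- suppressWarnings(as.numeric(dt$lon))
  dt$lat <- suppressWarnings(as.numeric(dt$lat))
  bad <- is.na(dt$date) | !is.finite(dt$value) | !is.finite(dt$lon) |
    !is.finite(dt$lat)
  if (any(bad)) {
    message(sum(bad), " station record(s) rejected (unparseable date or value)")
    dt <- dt[!bad, , drop = FALSE]
  }
  dt$network <- normalize_network(dt$network)
  rownames(dt) <- NULL
  dt
}

#' Read a cohort file
#'
#' Delimited text in the schema of [build_design()]; validates that all six
#' weekly residence coordinate pairs are present and ids unique (errors
#' name the offending subjects/columns).
#'
#' @param path file path.
#' @return a [cohort_table()].
#' @export
read_cohort_file <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  dt <- as.data.frame(data.table::fread(path,
                                        colClasses = list(character = "id")))
  build_design(dt)
}

#' Write station records / cohort rows
#'
#' Plain CSV writers matching the reader schemas.
#'
#' @param records,raw data.frames in the respective schemas.
#' @param path output path.
#' @export
write_station_file <- function(records, path) {
  data.table::fwrite(records[, STATION_COLUMNS], path)
  invisible(path)
}

#' @rdname write_station_file
#' @export
write_cohort_file <- function(raw, path) {
  data.table::fwrite(raw, path)
  invisible(path)
}

#' Write / read posterior draws
#'
#' One whitespace-free CSV per parameter block (rows = stored draws) plus
#' `manifest.json` recording the seed, configuration hash, package version
#' and block dimensions.  Writing is atomic (tmp-then-rename per file).
#' The round-trip is bit-lossless (full-precision decimal text).
#'
#' @param fit a [run_gibbs()] result.
#' @param dir output directory (created if needed).
#' @export
write_draws <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(fit$draws)) {
    tmp <- file.path(dir, paste0(".tmp_", nm, ".csv"))
    m <- fit$draws[[nm]]
    # 17 significant digits round-trips IEEE doubles exactly
    ch <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
    data.table::fwrite(as.data.frame(ch), tmp, quote = FALSE)
    file.rename(tmp, file.path(dir, paste0(nm, ".csv")))
  }
  cfg <- fit$config
  manifest <- list(
    package = "dsfm",
    version = as.character(utils::packageVersion("dsfm")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    M = fit$M, n_draws = fit$n_draws,
    dims = fit$dims,
    blocks = lapply(fit$draws, function(m) ncol(m)),
    pollutant_names = fit$pollutant_names,
    covariate_names = fit$covariate_names,
    accept = as.list(fit$accept))
  tmp <- file.path(dir, ".tmp_manifest.json")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_draws
#' @export
read_draws <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  draws <- lapply(stats::setNames(nm = names(manifest$blocks)), function(nm) {
    as.matrix(data.table::fread(file.path(dir, paste0(nm, ".csv"))))
  })
  structure(list(draws = lapply(draws, unname), manifest = manifest,
                 n_draws = manifest$n_draws, M = manifest$M,
                 dims = manifest$dims,
                 pollutant_names = manifest$pollutant_names,
                 covariate_names = manifest$covariate_names,
                 N = if (!is.null(manifest$blocks$beta))
                   manifest$blocks$exposure / (6 * manifest$M)),
            class = "pm_fit")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

#' Posterior summary table for a draw matrix
#'
#' Mean, SD, and 2.5% / 50% / 97.5% quantiles (linear-interpolation
#' convention) per column.
#'
#' @param draws draw matrix (rows = draws) or vector.
#' @param labels optional row labels.
#' @return data.frame with columns `mean`, `sd`, `q2.5`, `q50`, `q97.5`.
#' @export
summarize_draws <- function(draws, labels = NULL) {
  m <- as.matrix(draws)
  if (nrow(m) < 2L) stop("need at least two draws to summarize")
  out <- data.frame(
    mean = colMeans(m),
    sd = apply(m, 2, stats::sd),
    q2.5 = apply(m, 2, stats::quantile, probs = 0.025),
    q50 = apply(m, 2, stats::quantile, probs = 0.5),
    q97.5 = apply(m, 2, stats::quantile, probs = 0.975))
  rownames(out) <- labels %||% colnames(draws) %||%
    paste0("par", seq_len(ncol(m)))
  out
}

#' Posterior summaries of the health-model coefficients
#'
#' Covariate and weekly-exposure coefficient tables per defect on the
#' unit-variance reporting scale (each outcome rescaled by
#' `1 / sqrt(Omega_jj)` draw-wise), with the reporting contrast labels.
#'
#' @param fit a [run_gibbs()] result with health draws.
#' @return list of data.frames `palate`, `lip`, `weekly_palate`,
#'   `weekly_lip`, `correlation`.
#' @export
summarize_fit <- function(fit) {
  dr <- fit$draws
  if (is.null(dr$beta)) stop("fit has no health-model draws")
  q <- length(fit$covariate_names); M <- fit$M
  S <- nrow(dr$beta)
  sc <- cbind(sqrt(dr$omega[, 1]), sqrt(dr$omega[, 4]))
  beta1 <- dr$beta[, seq_len(q), drop = FALSE] / sc[, 1]
  beta2 <- dr$beta[, q + seq_len(q), drop = FALSE] / sc[, 2]
  w1 <- dr$w[, seq_len(6 * M), drop = FALSE] / sc[, 1]
  w2 <- dr$w[, 6 * M + seq_len(6 * M), drop = FALSE] / sc[, 2]
  rho <- dr$omega[, 2] / (sc[, 1] * sc[, 2])
  wk_labels <- paste0("Week ", rep(GESTATION_WEEKS, M),
                      if (M > 1) paste0(" factor ",
                                        rep(seq_len(M), each = 6)) else "")
  list(palate = summarize_draws(beta1, covariate_labels()),
       lip = summarize_draws(beta2, covariate_labels()),
       weekly_palate = summarize_draws(w1, wk_labels),
       weekly_lip = summarize_draws(w2, wk_labels),
       correlation = summarize_draws(matrix(rho, ncol = 1), "rho"))
}
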