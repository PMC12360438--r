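#' Read a tumor-volume measurement table
#'
#' Delimited text with header `time_days,volume_mm3,group,replicate`
#' (UTF-8, period decimal separator). Volumes must be positive and times
#' non-negative.
#'
#' @param path CSV file path.
#' @return A data frame of class `measurement_table`.
#' @export
read_measurements <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_measurement_table(x)
}

#' Coerce a data frame to a measurement table
#'
#' @param x Data frame with columns `time_days`, `volume_mm3`, `group`,
#'   `replicate`.
#' @return A validated `measurement_table`.
#' @export
as_measurement_table <- function(x) {
  need <- c("time_days", "volume_mm3", "group", "replicate")
  if (!all(need %in% names(x)))
    stop("measurement table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(x$volume_mm3 <= 0)) stop("volumes must be > 0", call. = FALSE)
  if (any(x$time_days < 0)) stop("times must be >= 0", call. = FALSE)
  class(x) <- c("measurement_table", "data.frame")
  x
}

#' Write a measurement table
#'
#' @param x A `measurement_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Calibrate the proliferation-oxygen coupling k1
#'
#' Scalar root-find on k1 so that the simulated untreated-control final
#' tumor volume matches the measured final volume (mean over replicates at
#' the last control time point) to within the requested relative tolerance.
#' All other parameters stay fixed, and the calibrated k1 is then used
#' unchanged across every arm.
#'
#' @param cfg A `sono_config`.
#' @param measurements A `measurement_table` containing a control group.
#' @param group Group label of the untreated controls (default
#'   `"control"`).
#' @param bounds Search interval for k1 (default `c(1e-4, 2)`).
#' @param rel_tol Relative tolerance on the matched final volume
#'   (default 0.005).
#' @param k1_tol Absolute tolerance of the root search on k1
#'   (default 5e-4).
#' @return A list with `k1`, `target_volume_mm3`, `achieved_volume_mm3`,
#'   `residual_rel`.
#' @export
calibrate_k1 <- function(cfg, measurements, group = "control",
                         bounds = c(1e-4, 2), rel_tol = 0.005,
                         k1_tol = 5e-4) {
  m <- measurements[measurements$group == group, , drop = FALSE]
  if (nrow(m) == 0) stop("no rows for group '", group, "'", call. = FALSE)
  t_final <- max(m$time_days)
  target <- mean(m$volume_mm3[m$time_days == t_final])
  cfg$numerics$horizon_h <- t_final * 24

  sim_final <- function(k1) {
    cfg$populations$k1 <- k1
    res <- run_protocol(cfg, treatment_schedule("control"))
    res$series$tumor_volume_mm3[nrow(res$series)]
  }
  f <- function(k1) sim_final(k1) - target
  flo <- f(bounds[1]); fhi <- f(bounds[2])
  if (flo * fhi > 0)
    stop(sprintf(paste0("no bracketing interval for k1 in [%g, %g]: ",
                        "simulated volumes %.1f and %.1f vs target %.1f"),
                 bounds[1], bounds[2], flo + target, fhi + target, target),
         call. = FALSE)
  root <- stats::uniroot(f, bounds, tol = k1_tol,
                         f.lower = flo, f.upper = fhi)
  achieved <- root$f.root + target
  res_rel <- abs(achieved - target) / target
  if (res_rel > rel_tol)
    warning(sprintf("calibration residual %.3f%% exceeds tolerance",
                    100 * res_rel), call. = FALSE)
  list(k1 = root$root, target_volume_mm3 = target,
       achieved_volume_mm3 = achieved, residual_rel = res_rel)
}

#' Coefficient of determination of model vs measurements
#'
#' R^2 = 1 - SS_res/SS_tot with SS_tot about the measurement mean; the
#' model curve is linearly interpolated to the measurement times. Values
#' can be negative for fits worse than the mean; they are reported as-is.
#'
#' @param model_time_days Model time grid, days.
#' @param model_volume Model volumes at `model_time_days`.
#' @param measurements A `measurement_table` (single group).
#' @return Scalar R^2 (<= 1).
#' @export
r_squared <- function(model_time_days, model_volume, measurements) {
  if (nrow(measurements) < 3)
    stop("need at least 3 measurement points for R^2", call. = FALSE)
  pred <- stats::approx(model_time_days, model_volume,
                        xout = measurements$time_days, rule = 2)$y
  obs <- measurements$volume_mm3
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else -Inf)
  1 - ss_res / ss_tot
}

#' Fold-change report versus control
#'
#' Expresses each arm's perfusion surrogate (mean functional vascular
#' density) and hypoxia percentage relative to the control arm at a given
#' time, as fold changes. A zero control value yields `NA` (undefined), not
#' infinity.
#'
#' @param runs Named list of [run_protocol()] results (must include
#'   `control`).
#' @param at_time_h Comparison time in hours (default: the config's report
#'   time).
#' @return A data frame with columns `arm`, `perfusion_fold`,
#'   `hypoxia_fold`, `volume_fold`.
#' @export
fold_change_report <- function(runs, at_time_h = NULL) {
  if (!"control" %in% names(runs)) stop("runs must include 'control'",
                                        call. = FALSE)
  if (is.null(at_time_h))
    at_time_h <- runs$control$config$report$time_h
  grab <- function(run, col) {
    s <- run$series
    stats::approx(s$time_h, s[[col]], xout = at_time_h, rule = 2)$y
  }
  ctrl_perf <- grab(runs$control, "perfusion_Sv_per_m")
  ctrl_hyp <- grab(runs$control, "hypoxia_percent")
  ctrl_vol <- grab(runs$control, "tumor_volume_mm3")
  fold <- function(x, ref) if (isTRUE(ref != 0)) x / ref else NA_real_
  do.call(rbind, lapply(names(runs), function(nm) {
    data.frame(
      arm = nm,
      perfusion_fold = fold(grab(runs[[nm]], "perfusion_Sv_per_m"),
                            ctrl_perf),
      hypoxia_fold = fold(grab(runs[[nm]], "hypoxia_percent"), ctrl_hyp),
      volume_fold = fold(grab(runs[[nm]], "tumor_volume_mm3"), ctrl_vol))
  }))
}

#' Generate a synthetic tumor-growth measurement fixture
#'
#' Simulates the requested arm, samples the volume curve at a regular
#' interval (2-4 days), and applies multiplicative log-normal noise with the
#' requested coefficient of variation — a synthetic stand-in for in-vivo
#' caliper measurements. Deterministic under the seed.
#'
#' @param cfg A `sono_config`.
#' @param k1_true The proliferation-oxygen coupling used for the simulated
#'   truth.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   noise (>= 0).
#' @param seed Integer RNG seed.
#' @param group Group label stored in the table (default `"control"`).
#' @param schedule Treatment schedule (default: untreated control).
#' @param sample_every_days Sampling interval in days (default 3).
#' @param n_replicates Number of replicate animals per time point
#'   (default 8).
#' @return A `measurement_table`.
#' @export
generate_fixture <- function(cfg, k1_true, noise_cv = 0.1, seed = 1,
                             group = "control", schedule = NULL,
                             sample_every_days = 3, n_replicates = 8) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (sample_every_days < 2 || sample_every_days > 4)
    stop("sampling interval must be 2-4 days", call. = FALSE)
  cfg$populations$k1 <- k1_true
  if (is.null(schedule)) schedule <- treatment_schedule(group)
  res <- run_protocol(cfg, schedule)
  s <- res$series
  t_days <- seq(0, max(s$time_h) / 24, by = sample_every_days)
  truth <- stats::approx(s$time_h / 24, s$tumor_volume_mm3,
                         xout = t_days)$y
  sdlog <- sqrt(log(1 + noise_cv^2))
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_replicates), function(rep) {
    noise <- if (noise_cv == 0) rep(1, length(t_days)) else
      stats::rlnorm(length(t_days), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    data.frame(time_days = t_days, volume_mm3 = truth * noise,
               group = group, replicate = rep)
  }))
  as_measurement_table(rows)
}

#' Write run outputs as tidy CSV plus a JSON manifest
#'
#' Writes `timeseries.csv` (long format: time_h, variable, value) and
#' `manifest.json` (arm, config hash, package version, wall time) into
#' `dir`.
#'
#' @param result A [run_protocol()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- result$series
  long <- stats::reshape(s, direction = "long",
                         varying = setdiff(names(s), "time_h"),
                         v.names = "value", timevar = "variable",
                         times = setdiff(names(s), "time_h"))
  long <- long[order(long$time_h), c("time_h", "variable", "value")]
  utils::write.csv(long, file.path(dir, "timeseries.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(arm = result$arm,
                   config_hash = config_hash(result$config),
                   package_version =
                     as.character(utils::packageVersion("sonomech")),
                   written_at = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Hash of a configuration
#'
#' MD5 of the deparsed configuration, for run manifests.
#'
#' @param cfg A `sono_config`.
#' @return Character hash.
#' @export
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg), f)
  unname(tools::md5sum(f))
}
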