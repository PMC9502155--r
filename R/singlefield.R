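# Single-field drift-tube calibration. At one drift voltage, arrival time
# is linear in the reduced CCS of the calibrant ions:
#   standard mode:  tA = slope * Omega'  + t0
#   enhanced mode:  tA = slope * (P/T) * Omega' + t0
# The enhanced mode moves the per-run pressure/temperature ratio into the
# regressor so that drift between the calibrant run and each sample run is
# corrected at application time. tims_scan mode is the standard fit with
# IMS scan numbers standing in for arrival times.

# match each calibrant of the run polarity to its best (most intense)
# feature; returns one row per matched calibrant
.match_calibrants <- function(features, calibrants, tol_ppm, polarity = NULL) {
  if (!is.null(polarity))
    calibrants <- calibrants[calibrants$polarity == polarity, , drop = FALSE]
  rows <- vector("list", nrow(calibrants))
  missing <- character()
  for (i in seq_len(nrow(calibrants))) {
    m <- match_features(features, calibrants$mz[i], tol_ppm)
    if (nrow(m) == 0L) {
      missing <- c(missing, calibrants$name[i])
      next
    }
    rows[[i]] <- data.frame(
      name = calibrants$name[i], mz_ref = calibrants$mz[i],
      charge_z = calibrants$z[i], ccs_ref = calibrants$ccs[i],
      polarity = calibrants$polarity[i],
      mz = m$mz[1L], arrival_time = m$arrival_time[1L],
      intensity = m$intensity[1L], mass_error_ppm = m$mass_error_ppm[1L],
      stringsAsFactors = FALSE)
  }
  list(points = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
       missing = missing)
}

#' Fit a single-field linear CCS calibration
#'
#' Matches calibrant ions in a calibrant-run feature table and fits
#' ordinary least squares of arrival time on the reduced CCS (standard
#' and tims_scan modes) or on the pressure/temperature-adjusted reduced
#' CCS (enhanced mode) of the matched calibrants.
#'
#' @param features Feature table of the calibrant run (`ims_features`).
#'   For `tims_scan` mode the `arrival_time` column holds IMS scan
#'   numbers instead of times.
#' @param calibrants Calibrant list (`name`, `mz`, `z`, `ccs`,
#'   `polarity`), as read by [read_calibrants_csv()].
#' @param conditions Frame metadata of the calibrant run; multiple rows
#'   are reduced to their mean pressure/temperature. Required fields:
#'   `polarity`, `timestamp`, `run_id`; `pressure_Torr` and
#'   `temperature_C` additionally for enhanced mode.
#' @param mode `"standard"`, `"enhanced"` or `"tims_scan"`.
#' @param gas Buffer gas of the measurement.
#' @param tol_ppm Calibrant matching tolerance (ppm); the most intense
#'   matching feature wins.
#' @return An object of class `ccs_cal_linear` (also `ccs_cal`) with the
#'   slope, intercept `t0`, R^2, the calibrant point table, the arrival
#'   time range spanned by the calibrants, and the run polarity,
#'   timestamp, pressure and temperature.
#' @export
fit_single_field <- function(features, calibrants, conditions,
                             mode = c("standard", "enhanced", "tims_scan"),
                             gas = buffer_gas("nitrogen"), tol_ppm = 20) {
  mode <- match.arg(mode)
  polarity <- conditions$polarity[1L]
  P <- mean(conditions$pressure_Torr)
  T_K <- mean(celsius_to_kelvin(conditions$temperature_C))
  if (mode == "enhanced" && (!is.finite(P) || !is.finite(T_K)))
    stop("enhanced mode requires pressure and temperature in `conditions`",
         call. = FALSE)
  matched <- .match_calibrants(features, calibrants, tol_ppm, polarity)
  pts <- matched$points
  if (is.null(pts) || nrow(pts) < 2L)
    stop("need at least 2 matched calibrants; missing: ",
         paste(matched$missing, collapse = ", "), call. = FALSE)
  ion_mass <- .ion_mass(pts$mz_ref, pts$charge_z, pts$polarity)
  pts$omega_prime <- pts$ccs_ref *
    .reduced_ccs_factor(pts$charge_z, ion_mass, gas$mass)
  pts$x <- switch(mode,
                  standard = pts$omega_prime,
                  tims_scan = pts$omega_prime,
                  enhanced = (P / T_K) * pts$omega_prime)
  fit <- stats::lm(arrival_time ~ x, data = pts)
  slope <- unname(stats::coef(fit)[2L])
  t0 <- unname(stats::coef(fit)[1L])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration failure: non-positive slope", call. = FALSE)
  r2 <- if (nrow(pts) == 2L) 1 else .lm_r2(fit, pts$arrival_time)
  structure(list(mode = mode, slope = slope, intercept_t0 = t0,
                 r_squared = r2, calibrant_points = pts,
                 tA_range = range(pts$arrival_time),
                 polarity = polarity, source_run = conditions$run_id[1L],
                 fit_timestamp = conditions$timestamp[1L],
                 pressure_Torr = P, temperature_K = T_K, gas = gas),
            class = c("ccs_cal_linear", "ccs_cal"))
}

#' @export
print.ccs_cal_linear <- function(x, ...) {
  cat(sprintf(paste0("Single-field CCS calibration (%s mode)\n",
                     "  run %s (%s), %d calibrants\n",
                     "  tA = %.6g * x + %.6g,  R^2 = %.6f\n"),
              x$mode, x$source_run, x$polarity, nrow(x$calibrant_points),
              x$slope, x$intercept_t0, x$r_squared))
  invisible(x)
}

#' @export
coef.ccs_cal_linear <- function(object, ...) {
  c(slope = object$slope, t0 = object$intercept_t0)
}

#' @export
summary.ccs_cal_linear <- function(object, ...) {
  print(object)
  cat("  calibrant points:\n")
  print(object$calibrant_points[, c("name", "mz", "arrival_time",
                                    "ccs_ref", "x")], digits = 6)
  invisible(object)
}

#' Diagnostic plot of a linear calibration curve
#'
#' @param x A `ccs_cal_linear` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ccs_cal_linear <- function(x, ...) {
  pts <- x$calibrant_points
  graphics::plot(pts$x, pts$arrival_time,
                 xlab = switch(x$mode, enhanced = "adjusted reduced CCS (P/T)",
                               "reduced CCS"),
                 ylab = if (x$mode == "tims_scan") "IMS scan" else
                   "arrival time (ms)",
                 pch = 19, ...)
  graphics::abline(x$intercept_t0, x$slope, col = 2)
  graphics::text(pts$x, pts$arrival_time, pts$name, pos = 3, cex = 0.7)
  invisible(x)
}

#' Assign the calibration for a sample run
#'
#' Chooses, among calibrations of the sample run's polarity, the one whose
#' acquisition timestamp is at or after the sample run's and closest to
#' it; if no calibration follows the sample, the closest preceding one is
#' used and flagged as a fallback. Ties are broken by run id.
#'
#' @param sample_meta One frame-metadata row (or anything with `polarity`
#'   and `timestamp`) of the sample run.
#' @param calibrations A list of `ccs_cal_linear` objects.
#' @return The chosen calibration. When the fallback (preceding) rule was
#'   used the returned object has attribute `fallback = TRUE`.
#' @export
assign_calibration_run <- function(sample_meta, calibrations) {
  pol <- sample_meta$polarity[1L]
  ts <- as.numeric(sample_meta$timestamp[1L])
  cals <- Filter(function(cc) cc$polarity == pol, calibrations)
  if (!length(cals))
    stop("no calibration run with polarity '", pol, "'", call. = FALSE)
  cal_ts <- vapply(cals, function(cc) as.numeric(cc$fit_timestamp), numeric(1))
  cal_id <- vapply(cals, function(cc) as.character(cc$source_run), character(1))
  after <- which(cal_ts >= ts)
  if (length(after)) {
    pick <- after[order(cal_ts[after] - ts, cal_id[after])][1L]
    out <- cals[[pick]]
    attr(out, "fallback") <- FALSE
  } else {
    pick <- order(ts - cal_ts, cal_id)[1L]
    out <- cals[[pick]]
    attr(out, "fallback") <- TRUE
  }
  out
}

#' Apply a single-field calibration to features (untargeted)
#'
#' Converts every feature's arrival time to a CCS through the calibration:
#' `x = (tA - t0) / slope`, then inverting the reduced-CCS scaling (and,
#' in enhanced mode, the sample run's own `P/T` factor). Every input
#' feature yields exactly one output record; features that cannot be
#' calibrated (`tA <= t0`) are flagged `invalid`, and features outside the
#' calibrant arrival-time range are flagged `extrapolated`, never dropped.
#'
#' @param features Feature table of the sample run.
#' @param calibration A `ccs_cal_linear` object.
#' @param conditions Frame metadata of the sample run; required in
#'   enhanced mode for the run's own pressure/temperature (multiple rows
#'   are averaged).
#' @param charge Default charge state for features without a `charge_z`
#'   column (default 1).
#' @return A [ccs_records()] data frame, one row per feature, in input
#'   order.
#' @export
calibrate_features <- function(features, calibration, conditions = NULL,
                               charge = 1L) {
  gas <- calibration$gas
  z <- if ("charge_z" %in% names(features) && !all(is.na(features$charge_z)))
    ifelse(is.na(features$charge_z), charge, features$charge_z)
  else rep(charge, nrow(features))
  ion_mass <- .ion_mass(features$mz, z, calibration$polarity)
  factor <- .reduced_ccs_factor(z, ion_mass, gas$mass)
  x <- (features$arrival_time - calibration$intercept_t0) / calibration$slope
  if (calibration$mode == "enhanced") {
    if (is.null(conditions))
      stop("enhanced mode needs the sample run's `conditions`", call. = FALSE)
    P_s <- mean(conditions$pressure_Torr)
    T_s <- mean(celsius_to_kelvin(conditions$temperature_C))
    omega_prime <- x * T_s / P_s
  } else {
    omega_prime <- x
  }
  ccs <- omega_prime / factor
  invalid <- !is.finite(ccs) | x <= 0
  extrap <- features$arrival_time < calibration$tA_range[1L] |
    features$arrival_time > calibration$tA_range[2L]
  flags <- character(nrow(features))
  flags[extrap] <- "extrapolated"
  flags[invalid] <- paste0(ifelse(nzchar(flags[invalid]),
                                  paste0(flags[invalid], ";"), ""), "invalid")
  ccs[invalid] <- NA_real_
  fallback <- isTRUE(attr(calibration, "fallback"))
  if (fallback)
    flags <- ifelse(nzchar(flags), paste0(flags, ";fallback_calibration"),
                    "fallback_calibration")
  ccs_records(data.frame(
    name = if ("name" %in% names(features)) features$name else
      sprintf("feature_%04d", seq_len(nrow(features))),
    adduct = NA_character_, mz = features$mz, charge_z = z, ccs = ccs,
    K0 = NA_real_, r_squared = calibration$r_squared, n_fields = NA_real_,
    intensity = features$intensity, mass_error_ppm = NA_real_,
    arrival_time = features$arrival_time, flags = flags,
    run_id = features$run_id,
    stringsAsFactors = FALSE))
}

#' Predict CCS from a single-field calibration
#'
#' @param object A `ccs_cal_linear` object.
#' @param features Feature table to calibrate.
#' @param conditions Sample-run metadata (enhanced mode).
#' @param ... Passed to [calibrate_features()].
#' @return A [ccs_records()] data frame.
#' @export
predict.ccs_cal_linear <- function(object, features, conditions = NULL, ...) {
  calibrate_features(features, object, conditions = conditions, ...)
}

#' Serialise a calibration to JSON
#'
#' Writes the mode, coefficients, R^2, calibrant points and validity
#' range for audit.
#'
#' @param calibration Any `ccs_cal` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(calibration, path) {
  obj <- unclass(calibration)
  obj$gas <- unclass(obj$gas)
  obj$fit_timestamp <- format(obj$fit_timestamp, "%Y-%m-%dT%H:%M:%S",
                              tz = "UTC")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
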