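# Traveling-wave (TWIMS/SLIM) calibration. The arrival-time/CCS relation
# is non-linear, so the reduced CCS of reference ions is fit either as a
# polynomial in the corrected arrival time, or through the linearized
# power law:
#   stage 1: ln Omega' = X ln t'A + ln Y        (log-log OLS)
#   stage 2: t''A = (t'A)^X * z / sqrt(mu)
#   stage 3: Omega = a t''A + b                 (final linear fit)
# with t'A = tA - C*sqrt(m/z)/1000 - t_acc (EDC delay C, ion accumulation
# time t_acc; C = 0 for SLIM).

# EDC + accumulation-time correction of arrival times (ms)
.twims_corrected_time <- function(tA, mz, edc, t_acc) {
  tA - edc * sqrt(mz) / 1000 - t_acc
}

#' Fit a polynomial TWIMS calibration
#'
#' Least-squares polynomial of the reduced CCS on the corrected arrival
#' time `t' = tA - t_acc`. The fit must be overdetermined: at least
#' `degree + 2` calibrant points are required, refusing exact
#' interpolation.
#'
#' @param features Feature table of the calibrant run.
#' @param calibrants Calibrant list (`name`, `mz`, `z`, `ccs`,
#'   `polarity`).
#' @param gas Buffer gas (helium for the SLIM fixtures).
#' @param degree Polynomial degree D >= 1 (default 2, quadratic).
#' @param t_acc Ion accumulation time in ms subtracted from every arrival
#'   time (e.g. 1000 for SLIM acquisitions; 0 otherwise).
#' @param tol_ppm Calibrant matching tolerance (ppm).
#' @param polarity Run polarity used to select calibrants (default
#'   `"positive"`).
#' @return An object of class `ccs_cal_poly` (also `ccs_cal`) with
#'   coefficients `x0..xD`, R^2, the calibrant points and the corrected
#'   arrival-time range.
#' @export
fit_twims_poly <- function(features, calibrants, gas = buffer_gas("helium"),
                           degree = 2L, t_acc = 0, tol_ppm = 20,
                           polarity = "positive") {
  if (degree < 1L) stop("degree must be >= 1", call. = FALSE)
  if (t_acc < 0) stop("t_acc must be >= 0", call. = FALSE)
  matched <- .match_calibrants(features, calibrants, tol_ppm, polarity)
  pts <- matched$points
  npt <- if (is.null(pts)) 0L else nrow(pts)
  if (npt <= degree + 1L)
    stop("polynomial of degree ", degree, " needs at least ", degree + 2L,
         " calibrant points (got ", npt, ")", call. = FALSE)
  pts$t_prime <- pts$arrival_time - t_acc
  if (any(pts$t_prime <= 0))
    stop("corrected arrival time <= 0 for calibrant ",
         pts$name[which(pts$t_prime <= 0)[1L]], call. = FALSE)
  ion_mass <- .ion_mass(pts$mz_ref, pts$charge_z, pts$polarity)
  pts$omega_prime <- pts$ccs_ref *
    .reduced_ccs_factor(pts$charge_z, ion_mass, gas$mass)
  fit <- stats::lm(omega_prime ~ stats::poly(t_prime, degree, raw = TRUE),
                   data = pts)
  coefs <- unname(stats::coef(fit))
  r2 <- .lm_r2(fit, pts$omega_prime)
  structure(list(mode = "polynomial", degree = degree, coefficients = coefs,
                 t_acc = t_acc, r_squared = r2, calibrant_points = pts,
                 t_prime_range = range(pts$t_prime),
                 tA_range = range(pts$arrival_time), polarity = polarity,
                 gas = gas),
            class = c("ccs_cal_poly", "ccs_cal"))
}

#' Fit a linearized power-law TWIMS calibration
#'
#' Three-stage fit: (1) OLS of `ln Omega'` on `ln t'` gives the power-law
#' exponent X and scale ln Y; (2) each calibrant's doubly corrected time
#' `t'' = (t')^X * z / sqrt(mu)` is computed with the ion/buffer-gas
#' reduced mass mu; (3) OLS of the reference CCS on `t''` gives the final
#' linear map `Omega = a t'' + b`. Arrival times are first corrected for
#' the EDC delay (`C * sqrt(m/z) / 1000`, Synapt instruments) and the ion
#' accumulation time.
#'
#' @inheritParams fit_twims_poly
#' @param edc EDC delay coefficient C (0 for SLIM).
#' @return An object of class `ccs_cal_power` (also `ccs_cal`) with
#'   `exponent_X`, `lnY`, `final_slope_a`, `final_intercept_b`, both R^2
#'   values, the calibrant points and the corrected-time range.
#' @export
fit_twims_power <- function(features, calibrants, gas = buffer_gas("helium"),
                            edc = 0, t_acc = 0, tol_ppm = 20,
                            polarity = "positive") {
  matched <- .match_calibrants(features, calibrants, tol_ppm, polarity)
  pts <- matched$points
  if (is.null(pts) || nrow(pts) < 3L)
    stop("power calibration needs at least 3 matched calibrants", call. = FALSE)
  pts$t_prime <- .twims_corrected_time(pts$arrival_time, pts$mz_ref, edc, t_acc)
  if (any(pts$t_prime <= 0))
    stop("corrected arrival time <= 0 for calibrant ",
         pts$name[which(pts$t_prime <= 0)[1L]], call. = FALSE)
  ion_mass <- .ion_mass(pts$mz_ref, pts$charge_z, pts$polarity)
  pts$omega_prime <- pts$ccs_ref *
    .reduced_ccs_factor(pts$charge_z, ion_mass, gas$mass)
  loglog <- stats::lm(log(omega_prime) ~ log(t_prime), data = pts)
  X <- unname(stats::coef(loglog)[2L])
  lnY <- unname(stats::coef(loglog)[1L])
  if (!is.finite(X) || X <= 0)
    stop("calibration failure: non-positive power-law exponent", call. = FALSE)
  r2_loglog <- .lm_r2(loglog, log(pts$omega_prime))
  mu <- reduced_mass(ion_mass, gas$mass)
  pts$t_dprime <- pts$t_prime^X * pts$charge_z / sqrt(mu)
  final <- stats::lm(ccs_ref ~ t_dprime, data = pts)
  a <- unname(stats::coef(final)[2L])
  b <- unname(stats::coef(final)[1L])
  if (!is.finite(a) || a <= 0)
    stop("calibration failure: non-positive final slope", call. = FALSE)
  structure(list(mode = "power", exponent_X = X, lnY = lnY,
                 final_slope_a = a, final_intercept_b = b, edc = edc,
                 t_acc = t_acc, r_squared_loglog = r2_loglog,
                 r_squared_final = .lm_r2(final, pts$ccs_ref),
                 calibrant_points = pts,
                 t_prime_range = range(pts$t_prime),
                 tA_range = range(pts$arrival_time), polarity = polarity,
                 gas = gas),
            class = c("ccs_cal_power", "ccs_cal"))
}

#' @export
print.ccs_cal_poly <- function(x, ...) {
  cat(sprintf(paste0("TWIMS polynomial CCS calibration (degree %d)\n",
                     "  %d calibrants, t_acc = %g ms, R^2 = %.6f\n"),
              x$degree, nrow(x$calibrant_points), x$t_acc, x$r_squared))
  invisible(x)
}

#' @export
print.ccs_cal_power <- function(x, ...) {
  cat(sprintf(paste0("TWIMS linearized power CCS calibration\n",
                     "  X = %.6g, ln Y = %.6g; Omega = %.6g t'' + %.6g\n",
                     "  %d calibrants, EDC = %g, t_acc = %g ms, ",
                     "R^2(log-log) = %.6f, R^2(final) = %.6f\n"),
              x$exponent_X, x$lnY, x$final_slope_a, x$final_intercept_b,
              nrow(x$calibrant_points), x$edc, x$t_acc, x$r_squared_loglog,
              x$r_squared_final))
  invisible(x)
}

#' @export
coef.ccs_cal_poly <- function(object, ...) {
  stats::setNames(object$coefficients,
                  paste0("x", seq_along(object$coefficients) - 1L))
}

#' @export
coef.ccs_cal_power <- function(object, ...) {
  c(X = object$exponent_X, lnY = object$lnY, a = object$final_slope_a,
    b = object$final_intercept_b)
}

# Horner evaluation of the stored polynomial at t'
.poly_eval <- function(coefs, t) {
  out <- rep(coefs[length(coefs)], length(t))
  for (d in rev(seq_len(length(coefs) - 1L))) out <- out * t + coefs[d]
  out
}

#' Apply a TWIMS calibration to features (untargeted)
#'
#' Converts arrival times to CCS through a fitted polynomial or power
#' calibration. Features whose corrected arrival time falls outside the
#' calibrant range are flagged `extrapolated`; non-positive corrected
#' times are flagged `invalid`. Every input feature yields one record.
#'
#' @param features Feature table of the sample run.
#' @param calibration A `ccs_cal_poly` or `ccs_cal_power` object.
#' @param charge Default charge for features lacking a `charge_z` column.
#' @return A [ccs_records()] data frame in input order.
#' @export
apply_twims_calibration <- function(features, calibration, charge = 1L) {
  gas <- calibration$gas
  z <- if ("charge_z" %in% names(features) && !all(is.na(features$charge_z)))
    ifelse(is.na(features$charge_z), charge, features$charge_z)
  else rep(charge, nrow(features))
  ion_mass <- .ion_mass(features$mz, z, calibration$polarity)
  if (inherits(calibration, "ccs_cal_poly")) {
    t_prime <- features$arrival_time - calibration$t_acc
    omega_prime <- .poly_eval(calibration$coefficients, t_prime)
    ccs <- omega_prime / .reduced_ccs_factor(z, ion_mass, gas$mass)
    r2 <- calibration$r_squared
  } else if (inherits(calibration, "ccs_cal_power")) {
    t_prime <- .twims_corrected_time(features$arrival_time, features$mz,
                                     calibration$edc, calibration$t_acc)
    mu <- reduced_mass(ion_mass, gas$mass)
    t_dprime <- ifelse(t_prime > 0, t_prime^calibration$exponent_X, NA_real_) *
      z / sqrt(mu)
    ccs <- calibration$final_slope_a * t_dprime + calibration$final_intercept_b
    r2 <- calibration$r_squared_final
  } else stop("unsupported calibration class", call. = FALSE)
  invalid <- t_prime <= 0 | !is.finite(ccs) | (!is.na(ccs) & ccs <= 0)
  extrap <- t_prime < calibration$t_prime_range[1L] |
    t_prime > calibration$t_prime_range[2L]
  flags <- character(nrow(features))
  flags[extrap] <- "extrapolated"
  flags[invalid] <- paste0(ifelse(nzchar(flags[invalid]),
                                  paste0(flags[invalid], ";"), ""), "invalid")
  ccs[invalid] <- NA_real_
  ccs_records(data.frame(
    name = if ("name" %in% names(features)) features$name else
      sprintf("feature_%04d", seq_len(nrow(features))),
    adduct = NA_character_, mz = features$mz, charge_z = z, ccs = ccs,
    K0 = NA_real_, r_squared = r2, n_fields = NA_real_,
    intensity = features$intensity, mass_error_ppm = NA_real_,
    arrival_time = features$arrival_time, flags = flags,
    run_id = features$run_id, stringsAsFactors = FALSE))
}

#' @export
predict.ccs_cal_poly <- function(object, features, ...) {
  apply_twims_calibration(features, object, ...)
}

#' @export
predict.ccs_cal_power <- function(object, features, ...) {
  apply_twims_calibration(features, object, ...)
}

#' Diagnostic plot of a TWIMS calibration curve
#'
#' Calibrant points with the fitted curve; the curve is drawn solid
#' within the calibrant range (interpolation) and dashed outside
#' (extrapolation).
#'
#' @param x A `ccs_cal_poly` or `ccs_cal_power` object.
#' @param extend Fraction of the calibrant range to extend on each side
#'   (default 0.3).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ccs_cal <- function(x, extend = 0.3, ...) {
  pts <- x$calibrant_points
  rng <- x$t_prime_range
  pad <- extend * diff(rng)
  grid_in <- seq(rng[1L], rng[2L], length.out = 100)
  grid_lo <- seq(max(1e-9, rng[1L] - pad), rng[1L], length.out = 20)
  grid_hi <- seq(rng[2L], rng[2L] + pad, length.out = 20)
  curve_at <- function(tp) {
    if (inherits(x, "ccs_cal_poly")) .poly_eval(x$coefficients, tp)
    else exp(x$lnY) * tp^x$exponent_X
  }
  graphics::plot(pts$t_prime, pts$omega_prime,
                 xlab = "corrected arrival time t' (ms)",
                 ylab = "reduced CCS", pch = 19,
                 xlim = range(c(grid_lo, grid_hi)), ...)
  graphics::lines(grid_in, curve_at(grid_in), col = 2)
  graphics::lines(grid_lo, curve_at(grid_lo), col = 2, lty = 2)
  graphics::lines(grid_hi, curve_at(grid_hi), col = 2, lty = 2)
  graphics::text(pts$t_prime, pts$omega_prime, pts$name, pos = 3, cex = 0.7)
  invisible(x)
}

#' Percent CCS difference against a reference
#'
#' `100 * |ccs_a - ccs_ref| / ccs_ref`, the comparison arithmetic used
#' when benchmarking calibrated CCS values against reference
#' determinations. Reported values are conventionally rounded to two
#' decimals.
#'
#' @param ccs_a CCS value(s) to compare.
#' @param ccs_ref Positive reference CCS value(s).
#' @return Absolute percent difference (vectorised, unrounded).
#' @export
#' @examples
#' round(delta_ccs_percent(63.53, 58.44), 2)  # 8.71
delta_ccs_percent <- function(ccs_a, ccs_ref) {
  if (any(!is.finite(ccs_ref)) || any(ccs_ref <= 0))
    stop("reference CCS must be positive", call. = FALSE)
  100 * abs(ccs_a - ccs_ref) / ccs_ref
}
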