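# Synthetic campaign generators with known ground truth. Every generator
# is a pure function of its parameters and seed: it saves and restores the
# caller's RNG state, so a fixed seed yields bit-identical output
# regardless of context.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# seeded per-run drift trajectories around a nominal value
.drift_series <- function(n, nominal, model, amount) {
  switch(model,
         constant = rep(nominal, n),
         linear = nominal * (1 + amount * seq(-1, 1, length.out = max(n, 2L))[seq_len(n)]),
         step = nominal * (1 + amount *
                             c(-1, 0, 1)[cut(seq_len(n), 3L, labels = FALSE)]),
         walk = nominal * (1 + amount *
                             cumsum(stats::rnorm(n)) / sqrt(max(n, 1L))),
         stop("unknown drift model '", model, "'", call. = FALSE))
}

#' Synthetic stepped-field campaign
#'
#' Generates a multi-field drift-tube campaign from ions with known CCS:
#' per ion and field, the arrival time follows the drift-time relation
#' `tA = x_field / K0 + t0` with `K0` derived from the true CCS at the
#' campaign temperature, optionally perturbed by multiplicative Gaussian
#' noise. Intensities are drawn from a seeded log-normal. Decoy features
#' at a controlled ppm offset can be injected to exercise the matching
#' tolerance.
#'
#' @param ions Data frame with `name`, `mz`, `charge_z`, `ccs` (true CCS,
#'   square Angstroms) and optionally `polarity` (default positive).
#' @param voltages Drift voltages of the fields (default the 7-field
#'   850-1450 V layout in 100 V increments).
#' @param pressure,temperature_C,drift_length Campaign drift-gas pressure
#'   (Torr), temperature (Celsius) and drift length (cm).
#' @param t0 True time outside the drift cell (ms).
#' @param noise_sd Gaussian arrival-time noise as a fraction of tA
#'   (default 0, noiseless).
#' @param decoy_ppm m/z offset of decoy features in ppm (`NULL` for
#'   none).
#' @param gas Buffer gas.
#' @param run_id Run label.
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return List with `features` (`ims_features`), `metadata`
#'   (`ims_frame_meta`) and `truth` (ions with their true `K0` at the
#'   campaign temperature and `t0`).
#' @export
synth_stepped_campaign <- function(ions, voltages = seq(850, 1450, by = 100),
                                   pressure = 3.95, temperature_C = 28,
                                   drift_length = 78.24, t0 = 0.3,
                                   noise_sd = 0, decoy_ppm = NULL,
                                   gas = buffer_gas("nitrogen"),
                                   run_id = "stepped_run1", seed = 1) {
  stopifnot(length(voltages) >= 2L)
  if (!"polarity" %in% names(ions)) ions$polarity <- "positive"
  .with_seed(seed, {
    nf <- length(voltages)
    meta <- .as_frame_meta(data.frame(
      run_id = run_id, field_id = seq_len(nf), voltage_V = voltages,
      pressure_Torr = pressure, temperature_C = temperature_C,
      length_cm = drift_length,
      timestamp = format(as.POSIXct("2024-03-01 08:00:00", tz = "UTC") +
                           30 * (seq_len(nf) - 1L), "%Y-%m-%dT%H:%M:%S"),
      polarity = ions$polarity[1L], stringsAsFactors = FALSE))
    x_axis <- build_field_axis(meta)
    T_K <- celsius_to_kelvin(temperature_C)
    truth <- ions
    truth$K0 <- vapply(seq_len(nrow(ions)), function(i) {
      ion <- list(charge_z = ions$charge_z[i],
                  ion_mass = .ion_mass(ions$mz[i], ions$charge_z[i],
                                       ions$polarity[i]))
      ccs_to_mobility(ions$ccs[i], ion, gas, T_K)
    }, numeric(1))
    truth$t0 <- t0
    base_int <- stats::rlnorm(nrow(ions), meanlog = log(1e4), sdlog = 0.5)
    rows <- list()
    for (i in seq_len(nrow(ions))) {
      tA <- unname(x_axis) / truth$K0[i] + t0
      if (noise_sd > 0) tA <- tA * (1 + stats::rnorm(nf, sd = noise_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        mz = ions$mz[i], arrival_time = tA,
        intensity = round(base_int[i] * stats::rlnorm(nf, sdlog = 0.1)),
        run_id = run_id, field_id = seq_len(nf), stringsAsFactors = FALSE)
      if (!is.null(decoy_ppm)) {
        rows[[length(rows) + 1L]] <- data.frame(
          mz = ions$mz[i] * (1 + decoy_ppm * 1e-6),
          arrival_time = stats::runif(nf, 0.5 * min(tA), 1.5 * max(tA)),
          intensity = round(base_int[i] * 0.5 *
                              stats::rlnorm(nf, sdlog = 0.1)),
          run_id = run_id, field_id = seq_len(nf), stringsAsFactors = FALSE)
      }
    }
    features <- .as_features(do.call(rbind, rows))
    list(features = features, metadata = meta, truth = truth)
  })
}

#' Synthetic single-field campaign with calibrant and sample runs
#'
#' Simulates an acquisition batch at a single drift voltage: calibrant
#' (tune-mix-style) runs are interleaved with sample runs on a timeline,
#' and drift-gas pressure and/or temperature drift across runs per the
#' chosen model. Arrival times follow the single-field linear relation
#' `tA = slope * (P_run / T_run) * Omega' + t0`: the run's own
#' pressure/temperature ratio enters the forward model, so enhanced-mode
#' calibration can correct the drift while standard-mode calibration
#' cannot.
#'
#' @param calibrants Calibrant list (`name`, `mz`, `z`, `ccs`,
#'   `polarity`).
#' @param samples Sample ions with true CCS (`name`, `mz`, `charge_z`,
#'   `ccs`; optional `polarity`).
#' @param n_sample_runs Number of sample runs.
#' @param cal_every A calibrant run is inserted before every
#'   `cal_every` sample runs (default 3).
#' @param pressure,temperature_C Nominal drift-gas conditions.
#' @param pressure_drift,temperature_drift Drift models, one of
#'   `"constant"`, `"linear"`, `"step"`, `"walk"`.
#' @param drift_amount Relative drift amplitude (default 0.02, i.e. 2%).
#' @param slope,t0 True calibration slope (ms per adjusted-reduced-CCS
#'   unit) and intercept (ms).
#' @param noise_sd Multiplicative Gaussian arrival-time noise fraction.
#' @param gas Buffer gas.
#' @param start Timeline start (UTC timestamp string).
#' @param run_interval_min Minutes between consecutive runs.
#' @param seed RNG seed.
#' @return List with `features` (all runs, `run_id` set), `metadata` (one
#'   row per run), `truth` (sample ions), `calibrant_runs` and
#'   `sample_runs` (run-id vectors).
#' @export
synth_single_field_campaign <- function(calibrants, samples,
                                        n_sample_runs = 9, cal_every = 3,
                                        pressure = 3.95, temperature_C = 28,
                                        pressure_drift = "constant",
                                        temperature_drift = "constant",
                                        drift_amount = 0.02, slope = 12,
                                        t0 = 0.3, noise_sd = 0,
                                        gas = buffer_gas("nitrogen"),
                                        start = "2024-03-01 08:00:00",
                                        run_interval_min = 30, seed = 1) {
  stopifnot(nrow(calibrants) >= 2L)
  if (!"polarity" %in% names(samples)) samples$polarity <- "positive"
  polarity <- samples$polarity[1L]
  .with_seed(seed, {
    n_cal <- ceiling(n_sample_runs / cal_every)
    kinds <- character()
    for (b in seq_len(n_cal)) {
      kinds <- c(kinds, "cal",
                 rep("sample", min(cal_every,
                                   n_sample_runs - (b - 1L) * cal_every)))
    }
    n_runs <- length(kinds)
    run_ids <- ifelse(kinds == "cal",
                      sprintf("cal_%02d", cumsum(kinds == "cal")),
                      sprintf("sample_%03d", cumsum(kinds == "sample")))
    P_run <- .drift_series(n_runs, pressure, pressure_drift, drift_amount)
    T_run <- .drift_series(n_runs, temperature_C, temperature_drift,
                           drift_amount * 10)  # drift in C, ~K scale
    ts <- as.POSIXct(start, tz = "UTC") +
      60 * run_interval_min * (seq_len(n_runs) - 1L)
    meta <- .as_frame_meta(data.frame(
      run_id = run_ids, field_id = 1L, voltage_V = 1450,
      pressure_Torr = P_run, temperature_C = T_run, length_cm = 78.24,
      timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"), polarity = polarity,
      stringsAsFactors = FALSE))
    cal_ion_mass <- .ion_mass(calibrants$mz, calibrants$z,
                              calibrants$polarity)
    cal_op <- calibrants$ccs *
      .reduced_ccs_factor(calibrants$z, cal_ion_mass, gas$mass)
    smp_ion_mass <- .ion_mass(samples$mz, samples$charge_z, samples$polarity)
    smp_op <- samples$ccs *
      .reduced_ccs_factor(samples$charge_z, smp_ion_mass, gas$mass)
    rows <- list()
    for (r in seq_len(n_runs)) {
      T_K <- celsius_to_kelvin(T_run[r])
      ratio <- P_run[r] / T_K
      if (kinds[r] == "cal") {
        mz <- calibrants$mz; op <- cal_op
        intensity <- round(stats::rlnorm(length(op), log(5e4), 0.3))
      } else {
        mz <- samples$mz; op <- smp_op
        intensity <- round(stats::rlnorm(length(op), log(2e4), 0.3))
      }
      tA <- slope * ratio * op + t0
      if (noise_sd > 0) tA <- tA * (1 + stats::rnorm(length(tA), sd = noise_sd))
      rows[[r]] <- data.frame(mz = mz, arrival_time = tA,
                              intensity = intensity, run_id = run_ids[r],
                              field_id = 1L, stringsAsFactors = FALSE)
    }
    list(features = .as_features(do.call(rbind, rows)), metadata = meta,
         truth = samples, calibrant_runs = run_ids[kinds == "cal"],
         sample_runs = run_ids[kinds == "sample"])
  })
}

#' Synthetic traveling-wave campaign
#'
#' Generates calibrant and sample features whose arrival times follow an
#' exact power law in the reduced CCS: `t' = (Omega'/Y)^(1/X)`, then
#' `tA = t' + C*sqrt(m/z)/1000 + t_acc` plus optional noise. On noiseless
#' output the linearized power fit recovers (X, Y) exactly, and the final
#' linear map has true slope `a = Y * sqrt(mB)` and intercept `b = 0`.
#'
#' @param calibrants Calibrant list (`name`, `mz`, `z`, `ccs`,
#'   `polarity`).
#' @param samples Optional sample ions with true CCS (`name`, `mz`,
#'   `charge_z`, `ccs`).
#' @param X True power-law exponent (> 0).
#' @param Y True power-law scale; `NULL` picks a value placing the median
#'   calibrant at t' = 200 ms.
#' @param t_acc Ion accumulation time added to every arrival time (ms).
#' @param edc EDC delay coefficient.
#' @param noise_sd Multiplicative Gaussian arrival-time noise fraction.
#' @param gas Buffer gas.
#' @param seed RNG seed.
#' @return List with `features` (calibrant + sample rows, `run_id` =
#'   `"twims_cal"` / `"twims_sample"`), `truth` (list with `X`, `Y`,
#'   `a`, `b`, and per-ion true CCS).
#' @export
synth_twims_campaign <- function(calibrants, samples = NULL, X = 0.55,
                                 Y = NULL, t_acc = 1000, edc = 0,
                                 noise_sd = 0, gas = buffer_gas("helium"),
                                 seed = 1) {
  stopifnot(X > 0)
  .with_seed(seed, {
    cal_ion_mass <- .ion_mass(calibrants$mz, calibrants$z,
                              calibrants$polarity)
    cal_op <- calibrants$ccs *
      .reduced_ccs_factor(calibrants$z, cal_ion_mass, gas$mass)
    if (is.null(Y)) Y <- stats::median(cal_op) / 200^X
    gen <- function(mz, z, op, run_id, meanlog) {
      t_prime <- (op / Y)^(1 / X)
      tA <- t_prime + edc * sqrt(mz) / 1000 + t_acc
      if (noise_sd > 0) tA <- tA * (1 + stats::rnorm(length(tA),
                                                     sd = noise_sd))
      data.frame(mz = mz, arrival_time = tA,
                 intensity = round(stats::rlnorm(length(mz), meanlog, 0.3)),
                 run_id = run_id, field_id = NA_integer_, charge_z = z,
                 stringsAsFactors = FALSE)
    }
    rows <- list(gen(calibrants$mz, calibrants$z, cal_op, "twims_cal",
                     log(5e4)))
    if (!is.null(samples)) {
      if (!"polarity" %in% names(samples)) samples$polarity <- "positive"
      smp_ion_mass <- .ion_mass(samples$mz, samples$charge_z,
                                samples$polarity)
      smp_op <- samples$ccs *
        .reduced_ccs_factor(samples$charge_z, smp_ion_mass, gas$mass)
      rows[[2L]] <- gen(samples$mz, samples$charge_z, smp_op,
                        "twims_sample", log(2e4))
    }
    list(features = .as_features(do.call(rbind, rows)),
         truth = list(X = X, Y = Y, a = Y * sqrt(gas$mass), b = 0,
                      t_acc = t_acc, edc = edc, calibrants = calibrants,
                      samples = samples))
  })
}
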