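# Single-field linear calibration: standard vs enhanced modes, calibrant
# run assignment, untargeted application.

make_cal_run <- function(calibrants, slope = 12, t0 = 0.3, P = 3.95,
                         T_C = 28, run_id = "cal_01",
                         ts = "2024-03-01T08:00:00",
                         gas = buffer_gas("nitrogen")) {
  T_K <- T_C + 273.15
  ion <- lapply(seq_len(nrow(calibrants)), function(i)
    ion_species(calibrants$mz[i], calibrants$z[i], calibrants$polarity[i]))
  op <- vapply(seq_len(nrow(calibrants)), function(i)
    reduced_ccs(calibrants$ccs[i], ion[[i]], gas), numeric(1))
  tA <- slope * (P / T_K) * op + t0
  feats <- ims_features(mz = calibrants$mz, arrival_time = tA,
                        intensity = 5e4, run_id = run_id)
  meta <- data.frame(run_id = run_id, field_id = 1L, voltage_V = 1450,
                     pressure_Torr = P, temperature_C = T_C,
                     length_cm = 78.24, timestamp = ts,
                     polarity = "positive", stringsAsFactors = FALSE)
  meta$timestamp <- as.POSIXct(sub("T", " ", ts), tz = "UTC")
  class(meta) <- c("ims_frame_meta", "data.frame")
  list(features = feats, meta = meta)
}

test_that("two exactly collinear calibrants are fit exactly", {
  cal2 <- tunemix_calibrants()[c(1, 5), ]
  run <- make_cal_run(cal2, slope = 10, t0 = 0.5)
  fit <- fit_single_field(run$features, cal2, run$meta, mode = "enhanced")
  expect_equal(fit$r_squared, 1)
  expect_equal(unname(coef(fit)["slope"]), 10, tolerance = 1e-9)
  expect_equal(unname(coef(fit)["t0"]), 0.5, tolerance = 1e-9)
})

test_that("synthetic tune-mix run recovers the generating line", {
  cal <- tunemix_calibrants()
  run <- make_cal_run(cal, slope = 12.34, t0 = 0.271)
  fit <- fit_single_field(run$features, cal, run$meta, mode = "enhanced")
  expect_equal(fit$slope, 12.34, tolerance = 1e-9)
  expect_equal(fit$intercept_t0, 0.271, tolerance = 1e-7)
  expect_gte(fit$r_squared, 1 - 1e-12)
})

test_that("fewer than two matched calibrants is an informative error", {
  cal <- tunemix_calibrants()
  run <- make_cal_run(cal[1, , drop = FALSE])
  expect_error(fit_single_field(run$features, cal, run$meta),
               "at least 2 matched calibrants")
})

test_that("standard and enhanced modes agree when P/T is constant", {
  cal <- tunemix_calibrants()
  smp <- data.frame(name = "rotenone", mz = 395.1489, charge_z = 1L,
                    ccs = 194.7, polarity = "positive")
  camp <- synth_single_field_campaign(cal, smp, n_sample_runs = 3,
                                      pressure_drift = "constant",
                                      temperature_drift = "constant",
                                      seed = 5)
  cal_feats <- camp$features[camp$features$run_id == "cal_01", ]
  cal_meta <- camp$metadata[camp$metadata$run_id == "cal_01", ]
  fit_std <- fit_single_field(cal_feats, cal, cal_meta, mode = "standard")
  fit_enh <- fit_single_field(cal_feats, cal, cal_meta, mode = "enhanced")
  smp_feats <- camp$features[camp$features$run_id == "sample_001", ]
  smp_meta <- camp$metadata[camp$metadata$run_id == "sample_001", ]
  ccs_std <- calibrate_features(smp_feats, fit_std)$ccs
  ccs_enh <- calibrate_features(smp_feats, fit_enh,
                                conditions = smp_meta)$ccs
  expect_equal(ccs_std, ccs_enh, tolerance = 1e-9)
  expect_equal(ccs_std, smp$ccs, tolerance = 1e-9)
})

test_that("calibrant self-prediction returns the reference CCS", {
  cal <- tunemix_calibrants()
  run <- make_cal_run(cal)
  fit <- fit_single_field(run$features, cal, run$meta, mode = "enhanced")
  rec <- calibrate_features(run$features, fit, conditions = run$meta)
  expect_equal(rec$ccs, cal$ccs, tolerance = 1e-9)
})

test_that("calibration-run assignment picks the following-closest same-polarity run", {
  cal <- tunemix_calibrants()
  mk <- function(run_id, ts) {
    run <- make_cal_run(cal, run_id = run_id, ts = ts)
    fit_single_field(run$features, cal, run$meta, mode = "standard")
  }
  cals <- list(mk("cal_A", "2024-03-01T09:00:00"),
               mk("cal_B", "2024-03-01T11:00:00"),
               mk("cal_C", "2024-03-01T15:00:00"))
  sample_meta <- data.frame(polarity = "positive",
                            timestamp = as.POSIXct("2024-03-01 10:00:00",
                                                   tz = "UTC"))
  pick <- assign_calibration_run(sample_meta, cals)
  expect_equal(pick$source_run, "cal_B")   # following and closest
  expect_false(attr(pick, "fallback"))
  # sample after the last calibration: preceding chosen, flagged fallback
  late <- data.frame(polarity = "positive",
                     timestamp = as.POSIXct("2024-03-01 23:00:00",
                                            tz = "UTC"))
  pick2 <- assign_calibration_run(late, cals)
  expect_equal(pick2$source_run, "cal_C")
  expect_true(attr(pick2, "fallback"))
  # polarity mismatch is an error
  neg <- data.frame(polarity = "negative", timestamp = late$timestamp)
  expect_error(assign_calibration_run(neg, cals), "polarity")
})

test_that("every feature yields a record; invalid and extrapolated are flagged", {
  cal <- tunemix_calibrants()
  run <- make_cal_run(cal)
  fit <- fit_single_field(run$features, cal, run$meta, mode = "standard")
  feats <- ims_features(mz = c(500, 500, 500),
                        arrival_time = c(0.05, mean(fit$tA_range),
                                         fit$tA_range[2] * 2),
                        intensity = 1)
  rec <- calibrate_features(feats, fit)
  expect_equal(nrow(rec), 3L)
  expect_match(rec$flags[1], "invalid")    # tA below t0
  expect_true(is.na(rec$ccs[1]))
  expect_equal(rec$flags[2], "")
  expect_match(rec$flags[3], "extrapolated")
  expect_false(is.na(rec$ccs[3]))
})

test_that("enhanced mode corrects pressure drift that standard mode cannot", {
  cal <- tunemix_calibrants()
  smp <- data.frame(name = "rotenone", mz = 395.1489, charge_z = 1L,
                    ccs = 194.7, polarity = "positive")
  camp <- synth_single_field_campaign(cal, smp, n_sample_runs = 9,
                                      cal_every = 3,
                                      pressure_drift = "step",
                                      drift_amount = 0.02,
                                      noise_sd = 0.0005, seed = 17)
  get_ccs <- function(mode) {
    cals <- lapply(camp$calibrant_runs, function(r)
      fit_single_field(camp$features[camp$features$run_id == r, ], cal,
                       camp$metadata[camp$metadata$run_id == r, ],
                       mode = mode))
    vapply(camp$sample_runs, function(r) {
      meta_r <- camp$metadata[camp$metadata$run_id == r, ]
      cc <- assign_calibration_run(meta_r, cals)
      calibrate_features(camp$features[camp$features$run_id == r, ], cc,
                         conditions = meta_r)$ccs
    }, numeric(1))
  }
  ccs_std <- get_ccs("standard")
  ccs_enh <- get_ccs("enhanced")
  rsd <- function(x) 100 * sd(x) / mean(x)
  expect_lt(rsd(ccs_enh), rsd(ccs_std))
  # enhanced values concentrate near truth
  expect_lt(abs(mean(ccs_enh) - smp$ccs) / smp$ccs, 0.005)
})

test_that("tims_scan mode calibrates scan numbers like arrival times", {
  cal <- tunemix_calibrants()
  gas <- buffer_gas("nitrogen")
  op <- vapply(seq_len(nrow(cal)), function(i)
    reduced_ccs(cal$ccs[i], ion_species(cal$mz[i], cal$z[i]), gas),
    numeric(1))
  scans <- 3.2 * op + 41  # scan number linear in reduced CCS
  feats <- ims_features(mz = cal$mz, arrival_time = scans, intensity = 1e4)
  meta <- data.frame(run_id = "cal_tims", field_id = 1L, voltage_V = 1,
                     pressure_Torr = 1, temperature_C = 25, length_cm = 1,
                     timestamp = as.POSIXct("2024-03-01 08:00:00",
                                            tz = "UTC"),
                     polarity = "positive")
  fit <- fit_single_field(feats, cal, meta, mode = "tims_scan")
  rec <- calibrate_features(feats, fit)
  expect_equal(rec$ccs, cal$ccs, tolerance = 1e-9)
})
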