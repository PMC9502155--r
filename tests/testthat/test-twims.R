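# Traveling-wave polynomial and linearized power-law calibration.

test_that("exact quadratic calibrants are recovered to 1e-9", {
  cal <- taa_calibrants()
  gas <- buffer_gas("helium")
  op <- vapply(seq_len(nrow(cal)), function(i)
    reduced_ccs(cal$ccs[i], ion_species(cal$mz[i], cal$z[i]), gas),
    numeric(1))
  coefs_true <- c(0.8, 0.012, 1.5e-5)
  # invert the quadratic numerically to plant arrival times
  t_prime <- vapply(op, function(o)
    uniroot(function(t) coefs_true[1] + coefs_true[2] * t +
              coefs_true[3] * t^2 - o, c(1, 1e5), tol = 1e-12)$root,
    numeric(1))
  t_acc <- 1000
  feats <- ims_features(mz = cal$mz, arrival_time = t_prime + t_acc,
                        intensity = 1e4)
  fit <- fit_twims_poly(feats, cal, gas, degree = 2, t_acc = t_acc)
  expect_equal(unname(coef(fit)), coefs_true, tolerance = 1e-7)
  expect_gte(fit$r_squared, 1 - 1e-12)
  # self-prediction returns reference CCS
  rec <- apply_twims_calibration(feats, fit)
  expect_equal(rec$ccs, cal$ccs, tolerance = 1e-9)
})

test_that("polynomial fits refuse exact interpolation", {
  cal <- taa_calibrants()[1:3, ]  # 3 points, degree 2 would interpolate
  feats <- ims_features(mz = cal$mz, arrival_time = c(100, 200, 300),
                        intensity = 1)
  expect_error(fit_twims_poly(feats, cal, degree = 2), "at least 4")
})

test_that("power-law round-trip recovers (X, Y, a, b) on noiseless data", {
  cal <- taa_calibrants()
  for (X_true in c(0.3, 0.55, 0.9, 1.5)) {
    camp <- synth_twims_campaign(cal, X = X_true, t_acc = 1000, seed = 8)
    fit <- fit_twims_power(camp$features, cal, t_acc = 1000)
    co <- coef(fit)
    expect_equal(unname(co["X"]), camp$truth$X, tolerance = 1e-6)
    expect_equal(exp(unname(co["lnY"])), camp$truth$Y, tolerance = 1e-6)
    expect_equal(unname(co["a"]), camp$truth$a, tolerance = 1e-6)
    expect_lt(abs(co["b"]), 1e-6 * camp$truth$a)
    expect_gte(fit$r_squared_final, 1 - 1e-12)
  }
})

test_that("EDC delay subtracts C*sqrt(m/z)/1000 before fitting", {
  cal <- taa_calibrants()
  edc <- 1.45
  with_edc <- synth_twims_campaign(cal, X = 0.5, t_acc = 0, edc = edc,
                                   seed = 4)
  without <- synth_twims_campaign(cal, X = 0.5, t_acc = 0, edc = 0,
                                  seed = 4)
  shift <- with_edc$features$arrival_time - without$features$arrival_time
  expect_equal(shift, edc * sqrt(cal$mz) / 1000, tolerance = 1e-12)
  # fits with matching edc agree with the no-delay fit
  f1 <- fit_twims_power(with_edc$features, cal, edc = edc)
  f2 <- fit_twims_power(without$features, cal, edc = 0)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
  # unaccounted delay degrades the log-log fit
  f3 <- fit_twims_power(with_edc$features, cal, edc = 0)
  expect_lt(f3$r_squared_loglog, f1$r_squared_loglog)
})

test_that("negative corrected times are refused with the ion named", {
  cal <- taa_calibrants()
  feats <- ims_features(mz = cal$mz, arrival_time = c(500, 1200, 1300,
                                                      1400, 1500),
                        intensity = 1)
  expect_error(fit_twims_power(feats, cal, t_acc = 1000), "TAA4")
})

test_that("features outside the calibrant range are flagged extrapolated, monotonically", {
  cal <- taa_calibrants()
  camp <- synth_twims_campaign(cal, X = 0.55, t_acc = 1000, seed = 9)
  fit <- fit_twims_power(camp$features, cal, t_acc = 1000)
  rng <- fit$t_prime_range
  t_test <- c(rng[1] * c(0.5, 0.8, 0.99), mean(rng), rng[2] * c(1.01, 1.3))
  feats <- ims_features(mz = 164.0574, arrival_time = t_test + 1000,
                        intensity = 1)
  rec <- apply_twims_calibration(feats, fit)
  flagged <- grepl("extrapolated", rec$flags)
  expect_equal(flagged, c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  # monotone: everything farther out on the same side stays flagged
  farther <- ims_features(mz = 164.0574,
                          arrival_time = c(rng[1] * 0.3, rng[2] * 2) + 1000,
                          intensity = 1)
  expect_true(all(grepl("extrapolated",
                        apply_twims_calibration(farther, fit)$flags)))
})

test_that("quadratic locally approximates a gentle power law within range", {
  cal <- taa_calibrants()
  camp <- synth_twims_campaign(cal, X = 0.55, t_acc = 1000, seed = 10)
  fit <- fit_twims_poly(camp$features, cal, degree = 2, t_acc = 1000)
  expect_gte(fit$r_squared, 0.999)
})

test_that("degree-1 polynomial on collinear points matches the planted line", {
  cal <- taa_calibrants()
  gas <- buffer_gas("helium")
  op <- vapply(seq_len(nrow(cal)), function(i)
    reduced_ccs(cal$ccs[i], ion_species(cal$mz[i], cal$z[i]), gas),
    numeric(1))
  t_prime <- (op - 0.2) / 0.01  # Omega' = 0.2 + 0.01 t'
  feats <- ims_features(mz = cal$mz, arrival_time = t_prime, intensity = 1)
  fit <- fit_twims_poly(feats, cal, gas, degree = 1, t_acc = 0)
  expect_equal(unname(coef(fit)), c(0.2, 0.01), tolerance = 1e-9)
  rec <- apply_twims_calibration(feats, fit)
  expect_equal(rec$ccs, cal$ccs, tolerance = 1e-9)
})

test_that("Horner and naive polynomial evaluation agree", {
  coefs <- c(0.8, 0.012, 1.5e-5, -2e-9)
  t <- seq(10, 500, length.out = 47)
  naive <- rowSums(outer(t, 0:3, `^`) *
                     matrix(coefs, nrow = length(t), ncol = 4, byrow = TRUE))
  horner <- imsccs:::.poly_eval(coefs, t)
  expect_equal(horner, naive, tolerance = 1e-12)
})

test_that("delta CCS percent reproduces published-style comparison cells", {
  # DTIMS vs SLIM comparison arithmetic, rounded to 2 decimals
  expect_equal(round(delta_ccs_percent(63.53, 58.44), 2), 8.71)
  expect_equal(round(delta_ccs_percent(58.51, 58.44), 2), 0.12)
  expect_equal(round(delta_ccs_percent(102.50, 104.90), 2), 2.29)
  expect_equal(round(delta_ccs_percent(104.50, 104.90), 2), 0.38)
  expect_equal(round(delta_ccs_percent(65.90, 63.85), 2), 3.21)
  expect_equal(round(delta_ccs_percent(62.41, 63.85), 2), 2.26)
  expect_equal(delta_ccs_percent(123.4, 123.4), 0)
  expect_error(delta_ccs_percent(100, -1), "positive")
})
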