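# Stepped-field combination search and regression.

test_that("field axis follows L^2 (273.15/760) P/(T V) per field", {
  meta <- make_meta()
  x <- build_field_axis(meta)
  expect_length(x, 7L)
  expect_true(all(diff(x) < 0))  # x strictly decreasing with voltage
  # independent per-field arithmetic
  T_K <- 28 + 273.15
  oracle <- 1000 * 78.24^2 * (273.15 / 760) * 3.95 /
    (T_K * seq(850, 1450, by = 100))
  expect_equal(unname(x), oracle, tolerance = 1e-12)
  # x proportional to 1/V at equal P, T
  meta2 <- make_meta(voltages = c(500, 1000))
  x2 <- build_field_axis(meta2)
  expect_equal(x2[[1]], 2 * x2[[2]], tolerance = 1e-12)
  expect_error(build_field_axis(make_meta(voltages = 850)), "2 fields")
})

test_that("noiseless planted ion is recovered exactly", {
  camp <- synth_stepped_campaign(tunemix_ions(), noise_sd = 0, seed = 11)
  fit <- fit_stepped_field(camp$features, camp$metadata, tunemix_targets())
  df <- as.data.frame(fit)
  protonated <- df[df$adduct == "[M+H]+", ]
  expect_equal(nrow(protonated), nrow(camp$truth))
  ord <- match(camp$truth$name, protonated$name)
  expect_equal(protonated$K0[ord], camp$truth$K0, tolerance = 1e-9)
  expect_equal(protonated$ccs[ord], camp$truth$ccs, tolerance = 1e-9)
  expect_true(all(protonated$r_squared >= 1 - 1e-12))
  expect_true(all(protonated$n_fields == 7L))
})

test_that("a grossly displaced candidate fails the threshold; dropping the field rescues it", {
  meta <- make_meta(voltages = seq(850, 1450, by = 150))  # 5 fields
  x <- build_field_axis(meta)
  K0 <- 1.3; t0 <- 0.25
  tA <- unname(x) / K0 + t0
  tA[3] <- tA[3] * 1.5  # gross outlier in field 3
  cands <- lapply(seq_along(x), function(i)
    ims_features(mz = 500, arrival_time = tA[i], intensity = 1000,
                 field_id = i))
  full <- enumerate_and_fit(cands, x, r2_threshold = 0.99,
                            min_fields = length(x))
  expect_equal(nrow(full), 0L)
  part <- enumerate_and_fit(cands, x, r2_threshold = 0.99, min_fields = 4L)
  expect_gte(nrow(part), 1L)
  # the best passing fit excludes field 3 and recovers K0
  expect_false(3L %in% part$fields[[1]])
  expect_equal(part$K0[1], K0, tolerance = 1e-9)
})

test_that("two planted conformers are resolved with correct feature pairing", {
  meta <- make_meta()
  x <- build_field_axis(meta)
  K0a <- 1.40; K0b <- 1.10; t0 <- 0.3
  cands <- lapply(seq_along(x), function(i) {
    ims_features(mz = 600, arrival_time = c(x[[i]] / K0a + t0,
                                            x[[i]] / K0b + t0),
                 intensity = c(5000, 2000), field_id = i)
  })
  fits <- enumerate_and_fit(cands, x, r2_threshold = 0.999999)
  expect_equal(nrow(fits), 2L)
  expect_equal(sort(fits$K0), sort(c(K0a, K0b)), tolerance = 1e-9)
  # each fit uses features of one conformer only (7 fields each)
  expect_true(all(fits$n_fields == 7L))
})

test_that("combination search matches a brute-force independent enumeration", {
  # independent oracle: recursive enumeration + lm(), <= 3 candidates per
  # field, <= 5 fields, skips allowed
  brute_force <- function(cands, x, thr, min_fields) {
    nf <- length(x)
    results <- list()
    recurse <- function(i, idx) {
      if (i > nf) {
        used <- which(idx > 0)
        if (length(used) < max(2L, min_fields)) return()
        xx <- x[used]
        yy <- vapply(used, function(k) cands[[k]]$arrival_time[idx[k]],
                     numeric(1))
        fit <- stats::lm(yy ~ xx)
        r2 <- suppressWarnings(summary(fit)$r.squared)
        sl <- unname(coef(fit)[2])
        if (is.finite(r2) && r2 >= thr && is.finite(sl) && sl > 0)
          results[[length(results) + 1L]] <<- list(idx = idx, K0 = 1 / sl)
        return()
      }
      for (j in 0:nrow(cands[[i]])) {
        if (j == 0 && min_fields >= nf) next
        recurse(i + 1L, c(idx, j))
      }
    }
    recurse(1L, integer(0))
    results
  }

  set.seed(99)
  for (rep in 1:4) {
    nf <- sample(3:5, 1)
    meta <- make_meta(voltages = seq(850, by = 120, length.out = nf))
    x <- build_field_axis(meta)
    K0 <- runif(1, 0.8, 1.8)
    cands <- lapply(seq_len(nf), function(i) {
      nc <- sample(1:3, 1)
      # one near-true candidate plus noise candidates
      tA <- c(x[[i]] / K0 + 0.3 + rnorm(1, sd = 1e-4),
              runif(nc - 1, 5, 60))
      ims_features(mz = 500, arrival_time = tA,
                   intensity = round(runif(nc, 1e2, 1e5)), field_id = i)
    })
    for (min_fields in c(nf, nf - 1L)) {
      got <- enumerate_and_fit(cands, x, r2_threshold = 0.99,
                               min_fields = min_fields)
      want <- brute_force(cands, x, 0.99, min_fields)
      expect_equal(nrow(got), length(want))
      expect_equal(sort(got$K0),
                   sort(vapply(want, `[[`, numeric(1), "K0")),
                   tolerance = 1e-9)
    }
  }
})

test_that("combination count stays within the rank-limit bound", {
  # with rank limit r and f fields, at most (r+1)^f combinations exist
  meta <- make_meta(voltages = seq(850, 1450, by = 200))
  x <- build_field_axis(meta)
  f <- length(x); r <- 3L
  cands <- lapply(seq_len(f), function(i)
    ims_features(mz = 500, arrival_time = runif(r, 10, 40),
                 intensity = round(runif(r, 1, 1e4)), field_id = i))
  fits <- enumerate_and_fit(cands, x, r2_threshold = 1e-9, min_fields = 2L)
  expect_lte(nrow(fits), (r + 1L)^f)
})

test_that("near-duplicate conformers are merged keeping the higher r-squared", {
  camp <- synth_stepped_campaign(tunemix_ions()[1, , drop = FALSE],
                                 noise_sd = 0, decoy_ppm = 5, seed = 3)
  # decoys at 5 ppm fall inside the 20 ppm tolerance and create spurious
  # combinations; after merging, the true conformer must dominate
  fit <- fit_stepped_field(camp$features, camp$metadata,
                           tunemix_targets()[1, , drop = FALSE])
  df <- as.data.frame(fit)
  best <- df[df$adduct == "[M+H]+", ][1, ]
  expect_equal(best$K0, camp$truth$K0[1], tolerance = 1e-6)
})

test_that("replicate summary computes mean and sample-sd RSD", {
  recs <- data.frame(name = "x", adduct = "[M+H]+",
                     ccs = c(154.0, 154.6, 153.5))
  s <- summarize_replicates(recs)
  expect_equal(s$mean_ccs, 154.0333333333333, tolerance = 1e-12)
  expect_equal(s$rsd_pct, 0.3575570578199138, tolerance = 1e-10)
  # identical replicates: zero RSD
  s0 <- summarize_replicates(data.frame(name = "y", adduct = "[M+H]+",
                                        ccs = c(100, 100, 100)))
  expect_equal(s0$rsd_pct, 0)
  # single replicate flagged
  s1 <- summarize_replicates(data.frame(name = "z", adduct = "[M+H]+",
                                        ccs = 200))
  expect_equal(s1$mean_ccs, 200)
  expect_equal(s1$rsd_pct, 0)
  expect_match(s1$flags, "single_replicate")
})
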