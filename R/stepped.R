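# Stepped-field drift-tube CCS determination: arrival time is regressed on
# the per-field term x = 1000 * L^2 * (273.15/760) * P / (T * V) (ms units)
# so that tA = x / K0 + t0 holds exactly in the low-field limit. A
# combination search over per-field candidate features finds the feature
# set(s) whose regression exceeds the R^2 threshold; each passing fit is a
# conformer.

#' Stepped-field regressor axis
#'
#' Computes, per field, the x-value `1000 * L^2 * (273.15/760) * P /
#' (T_K * V)` (L in cm, P in Torr, V in V, T in K) so that arrival time in
#' ms satisfies `tA = x / K0 + t0` with K0 in cm^2/(V s). Temperature is
#' kept inside the regressor per field; folding it in is exact under the
#' drift-time relation and removes bias when T drifts between fields.
#'
#' @param meta An `ims_frame_meta` data frame with at least two fields at
#'   distinct drift voltages.
#' @return Named numeric vector of x-values, names = `field_id`, ordered
#'   by field id.
#' @export
build_field_axis <- function(meta) {
  if (nrow(meta) < 2L || length(unique(meta$voltage_V)) < 2L)
    stop("need at least 2 fields with distinct drift voltages", call. = FALSE)
  meta <- meta[order(meta$field_id), , drop = FALSE]
  T_K <- celsius_to_kelvin(meta$temperature_C)
  x <- 1000 * meta$length_cm^2 * (.ims_const$standard_T / .ims_const$standard_P) *
    meta$pressure_Torr / (T_K * meta$voltage_V)
  stats::setNames(x, meta$field_id)
}

# R^2 of a fitted lm computed directly from residuals (avoids the
# "essentially perfect fit" warning on exact synthetic data)
.lm_r2 <- function(fit, y) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  max(0, min(1, 1 - sum(stats::residuals(fit)^2) / ss_tot))
}

# plain OLS of y on x with slope/intercept/r2; r2 = 1 for a perfect
# 2-point fit (ss_res = 0)
.ols_fit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(NULL)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot == 0) NA_real_ else max(0, min(1, 1 - ss_res / ss_tot))
  list(slope = slope, intercept = intercept, r_squared = r2, n = n)
}

#' Combination search and regression over per-field candidates
#'
#' Enumerates every combination taking at most one candidate feature per
#' field from at least `min_fields` fields, fits ordinary least squares of
#' arrival time on the field axis for each, and keeps fits with
#' `r_squared >= r2_threshold` and a positive slope (K0 = 1/slope must be
#' physical). Each passing fit is a candidate conformer.
#'
#' @param candidates Named list (by field id, matching `names(x_axis)`) of
#'   `ims_features` data frames, already rank-limited.
#' @param x_axis Field axis from [build_field_axis()].
#' @param r2_threshold Minimum R^2 for a fit to be kept (default 0.99).
#' @param min_fields Minimum number of fields a combination must span;
#'   default all fields (no skipping).
#' @return Data frame of passing fits sorted by descending `r_squared`
#'   then descending summed intensity, with a list-column `features`
#'   holding the chosen feature rows of each fit. Zero rows when no
#'   combination passes.
#' @export
enumerate_and_fit <- function(candidates, x_axis, r2_threshold = 0.99,
                              min_fields = length(x_axis)) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must be in (0, 1]", call. = FALSE)
  nf <- length(x_axis)
  stopifnot(length(candidates) == nf)
  min_fields <- max(2L, as.integer(min_fields))
  counts <- vapply(candidates, nrow, integer(1))
  # index 0 = skip this field (only allowed when min_fields < nf)
  choices <- lapply(seq_len(nf), function(i) {
    if (min_fields < nf) 0:counts[i] else seq_len(counts[i])
  })
  if (any(vapply(choices, length, integer(1)) == 0L))
    return(.empty_fits())
  grid <- as.matrix(expand.grid(choices, KEEP.OUT.ATTRS = FALSE))
  keep <- rowSums(grid > 0) >= min_fields
  grid <- grid[keep, , drop = FALSE]
  fits <- vector("list", nrow(grid))
  nfit <- 0L
  for (g in seq_len(nrow(grid))) {
    idx <- grid[g, ]
    used <- which(idx > 0)
    if (length(used) < 2L) next
    x <- x_axis[used]
    y <- vapply(used, function(i) candidates[[i]]$arrival_time[idx[i]],
                numeric(1))
    fit <- .ols_fit(x, y)
    if (is.null(fit) || is.na(fit$r_squared)) next
    if (fit$r_squared < r2_threshold) next
    if (fit$slope <= 0) next  # unphysical mobility; discard
    feats <- do.call(rbind, lapply(used, function(i)
      candidates[[i]][idx[i], c("mz", "arrival_time", "intensity", "run_id",
                                "field_id"), drop = FALSE]))
    feats$field_id <- as.integer(names(x_axis))[used]
    nfit <- nfit + 1L
    fits[[nfit]] <- list(slope = fit$slope, intercept_t0 = fit$intercept,
                         r_squared = fit$r_squared, K0 = 1 / fit$slope,
                         n_fields = length(used),
                         sum_intensity = sum(feats$intensity),
                         fields = as.integer(names(x_axis))[used],
                         features = feats)
  }
  if (nfit == 0L) return(.empty_fits())
  fits <- fits[seq_len(nfit)]
  out <- data.frame(
    slope = vapply(fits, `[[`, numeric(1), "slope"),
    intercept_t0 = vapply(fits, `[[`, numeric(1), "intercept_t0"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    K0 = vapply(fits, `[[`, numeric(1), "K0"),
    n_fields = vapply(fits, `[[`, integer(1), "n_fields"),
    sum_intensity = vapply(fits, `[[`, numeric(1), "sum_intensity"),
    stringsAsFactors = FALSE)
  out$fields <- lapply(fits, `[[`, "fields")
  out$features <- lapply(fits, `[[`, "features")
  ord <- order(-out$r_squared, -out$sum_intensity)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_fits <- function() {
  out <- data.frame(slope = numeric(), intercept_t0 = numeric(),
                    r_squared = numeric(), K0 = numeric(),
                    n_fields = integer(), sum_intensity = numeric(),
                    stringsAsFactors = FALSE)
  out$fields <- list()
  out$features <- list()
  out
}

# merge near-duplicate conformers: CCS within `tol` relative AND sharing
# at least half their features -> keep the higher-r2 fit
.merge_conformers <- function(fits, tol = 0.005) {
  if (nrow(fits) <= 1L) return(fits)
  feat_key <- lapply(fits$features, function(f)
    paste(f$field_id, signif(f$arrival_time, 12), signif(f$mz, 12)))
  drop <- rep(FALSE, nrow(fits))
  for (i in seq_len(nrow(fits) - 1L)) {
    if (drop[i]) next
    for (j in seq((i + 1L), nrow(fits))) {
      if (drop[j]) next
      if (abs(fits$ccs[i] - fits$ccs[j]) / fits$ccs[i] >= tol) next
      shared <- length(intersect(feat_key[[i]], feat_key[[j]]))
      if (shared * 2L >= min(length(feat_key[[i]]), length(feat_key[[j]])))
        drop[j] <- TRUE  # fits already sorted by descending r2
    }
  }
  fits[!drop, , drop = FALSE]
}

#' Fit stepped-field CCS for a set of target molecules
#'
#' Full stepped-field pipeline for one run: generate adduct ions for each
#' target, match features per field within the m/z tolerance, limit
#' candidates by intensity rank, run the combination search and keep the
#' regression fits passing the R^2 threshold. K0 is the reciprocal slope;
#' the CCS is evaluated by the Mason-Schamp relation at the mean
#' drift-gas temperature of the fields entering each fit. Near-duplicate
#' conformers (CCS within 0.5% relative, sharing at least half their
#' features) are merged, keeping the higher-R^2 fit.
#'
#' @param features An `ims_features` data frame with a `field_id` column.
#' @param meta Frame metadata (`ims_frame_meta`) for the same run.
#' @param targets Target molecules (`name`, `neutral_mass`).
#' @param adducts Adduct table; defaults to [default_adducts()].
#' @param tol_ppm m/z matching tolerance (ppm).
#' @param r2_threshold Minimum R^2 (default 0.99).
#' @param max_rank Per-field intensity-rank limit on candidates.
#' @param min_fields Minimum fields per combination; default all.
#' @param gas Buffer gas (default nitrogen).
#' @param merge_ccs_tol Relative CCS tolerance for duplicate-conformer
#'   merging (default 0.005); set to 0 to disable merging.
#' @return An object of class `stepped_ccs`: a list with `fits` (one
#'   entry per target ion, each a fit table as from [enumerate_and_fit()]
#'   with added `ccs` and `T_K` columns), `target_ions`, `x_axis`,
#'   `meta` and the parameters used. Use [as.data.frame()] (or
#'   [ccs_records()]) to flatten to a result table.
#' @export
fit_stepped_field <- function(features, meta, targets,
                              adducts = default_adducts(), tol_ppm = 20,
                              r2_threshold = 0.99, max_rank = 3,
                              min_fields = NULL,
                              gas = buffer_gas("nitrogen"),
                              merge_ccs_tol = 0.005) {
  x_axis <- build_field_axis(meta)
  meta <- meta[order(meta$field_id), , drop = FALSE]
  T_K_by_field <- stats::setNames(celsius_to_kelvin(meta$temperature_C),
                                  meta$field_id)
  polarity <- meta$polarity[1L]
  if (is.null(min_fields)) min_fields <- length(x_axis)
  ions <- generate_target_ions(targets, adducts, polarity = polarity)
  fits <- vector("list", nrow(ions))
  for (k in seq_len(nrow(ions))) {
    per_field <- lapply(names(x_axis), function(fid) {
      ff <- features[!is.na(features$field_id) &
                       features$field_id == as.integer(fid), , drop = FALSE]
      m <- match_features(ff, ions$expected_mz[k], tol_ppm)
      limit_by_intensity_rank(m, max_rank)
    })
    fit <- enumerate_and_fit(per_field, x_axis, r2_threshold, min_fields)
    if (nrow(fit)) {
      fit$T_K <- vapply(fit$fields, function(f)
        mean(T_K_by_field[as.character(f)]), numeric(1))
      ion <- list(charge_z = ions$charge_z[k], ion_mass = ions$ion_mass[k])
      fit$ccs <- vapply(seq_len(nrow(fit)), function(i)
        mobility_to_ccs(fit$K0[i], ion, gas, fit$T_K[i]), numeric(1))
      if (merge_ccs_tol > 0) fit <- .merge_conformers(fit, merge_ccs_tol)
      rownames(fit) <- NULL
    }
    fits[[k]] <- fit
  }
  structure(list(fits = fits, target_ions = ions, x_axis = x_axis,
                 meta = meta, gas = gas,
                 params = list(tol_ppm = tol_ppm, r2_threshold = r2_threshold,
                               max_rank = max_rank, min_fields = min_fields,
                               merge_ccs_tol = merge_ccs_tol)),
            class = "stepped_ccs")
}

#' @export
print.stepped_ccs <- function(x, ...) {
  n_conf <- sum(vapply(x$fits, nrow, integer(1)))
  cat(sprintf(paste0("Stepped-field CCS fit: %d target ion(s), %d field(s), ",
                     "%d conformer(s) passing R^2 >= %.3g\n"),
              nrow(x$target_ions), length(x$x_axis), n_conf,
              x$params$r2_threshold))
  invisible(x)
}

#' @export
summary.stepped_ccs <- function(object, ...) {
  df <- as.data.frame(object)
  cat("Stepped-field CCS results\n")
  if (nrow(df) == 0L) {
    cat("  no conformer passed the R^2 threshold\n")
  } else {
    print(df[, c("name", "adduct", "mz", "ccs", "K0", "r_squared",
                 "n_fields")], digits = 6)
  }
  invisible(df)
}

#' Flatten stepped-field fits to a CCS result table
#'
#' @param x A `stepped_ccs` object.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A [ccs_records()] data frame, one row per passing conformer.
#'   Conformers spanning fewer than all fields carry the `low_fields`
#'   flag.
#' @export
as.data.frame.stepped_ccs <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  rows <- list()
  nf_all <- length(x$x_axis)
  for (k in seq_len(nrow(x$target_ions))) {
    fit <- x$fits[[k]]
    if (nrow(fit) == 0L) next
    ion <- x$target_ions[k, ]
    for (i in seq_len(nrow(fit))) {
      feats <- fit$features[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        name = ion$name, adduct = ion$adduct, mz = ion$expected_mz,
        charge_z = ion$charge_z, ccs = fit$ccs[i], K0 = fit$K0[i],
        r_squared = fit$r_squared[i], n_fields = fit$n_fields[i],
        intensity = fit$sum_intensity[i],
        mass_error_ppm = mean((feats$mz - ion$expected_mz) /
                                ion$expected_mz * 1e6),
        arrival_time = mean(feats$arrival_time),
        flags = if (fit$n_fields[i] < nf_all) "low_fields" else "",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(ccs_records(data.frame(name = character())))
  ccs_records(do.call(rbind, rows))
}

#' Diagnostic plot of stepped-field regressions
#'
#' Draws the field axis against arrival time with the chosen features and
#' the fitted regression line of each passing conformer.
#'
#' @param x A `stepped_ccs` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.stepped_ccs <- function(x, ...) {
  all_fits <- do.call(rbind, lapply(seq_along(x$fits), function(k) {
    f <- x$fits[[k]]
    if (nrow(f) == 0L) return(NULL)
    do.call(rbind, lapply(f$features, function(d)
      data.frame(x = x$x_axis[as.character(d$field_id)],
                 y = d$arrival_time)))
  }))
  if (is.null(all_fits) || nrow(all_fits) == 0L) {
    graphics::plot.new(); graphics::title("no passing fits"); return(invisible(x))
  }
  graphics::plot(all_fits$x, all_fits$y, xlab = "field term x (ms units)",
                 ylab = "arrival time (ms)", pch = 19, ...)
  cols <- 1L
  for (k in seq_along(x$fits)) {
    f <- x$fits[[k]]
    for (i in seq_len(nrow(f))) {
      graphics::abline(f$intercept_t0[i], f$slope[i], col = cols, lty = 2)
      cols <- cols + 1L
    }
  }
  invisible(x)
}

#' Replicate statistics of CCS determinations
#'
#' Aggregates CCS records over technical replicates of the same molecule
#' and adduct: arithmetic mean and percent relative standard deviation
#' (sample standard deviation, n-1 denominator). Groups with a single
#' replicate report an RSD of 0 and carry the `single_replicate` flag.
#'
#' @param records A [ccs_records()] data frame (or anything with `name`,
#'   `adduct`, `ccs`).
#' @return Data frame with `name`, `adduct`, `n`, `mean_ccs`, `rsd_pct`,
#'   `flags`, sorted by name then adduct.
#' @export
#' @examples
#' recs <- data.frame(name = "x", adduct = "[M+H]+",
#'                    ccs = c(154.0, 154.6, 153.5))
#' summarize_replicates(recs)
summarize_replicates <- function(records) {
  records <- records[!is.na(records$ccs), , drop = FALSE]
  if (nrow(records) == 0L)
    return(data.frame(name = character(), adduct = character(),
                      n = integer(), mean_ccs = numeric(),
                      rsd_pct = numeric(), flags = character(),
                      stringsAsFactors = FALSE))
  records$adduct[is.na(records$adduct)] <- ""
  key <- interaction(records$name, records$adduct, drop = TRUE, sep = "\r")
  groups <- split(records, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    n <- nrow(g)
    m <- mean(g$ccs)
    rsd <- if (n > 1L) 100 * stats::sd(g$ccs) / m else 0
    data.frame(name = g$name[1L], adduct = g$adduct[1L], n = n,
               mean_ccs = m, rsd_pct = rsd,
               flags = if (n == 1L) "single_replicate" else "",
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$name, out$adduct, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
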