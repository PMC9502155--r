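# Orchestration: configuration validation, the three workflows
# (stepped-field, single-field, TWIMS) and deterministic report emission.

.config_keys <- c("workflow", "features", "metadata", "targets", "calibrants",
                  "out_dir", "tolerance_ppm", "r2_threshold", "mode",
                  "degree", "t_acc", "edc", "gas", "gas_mass", "max_rank",
                  "min_fields", "charge", "adducts", "calibrant_run_pattern",
                  "plots", "seed")

.config_defaults <- list(tolerance_ppm = 20, r2_threshold = 0.99,
                         mode = "standard", degree = 2L, t_acc = 0, edc = 0,
                         gas = "nitrogen", max_rank = 3, charge = 1L,
                         calibrant_run_pattern = "^cal", plots = FALSE)

#' Read and validate a run configuration
#'
#' Accepts a YAML file path or a named list. Unknown keys are rejected;
#' missing optional keys receive documented defaults (m/z tolerance 20
#' ppm, R^2 threshold 0.99, standard mode, polynomial degree 2, nitrogen
#' buffer gas, intensity-rank limit 3).
#'
#' @param config Path to a YAML configuration file, or a named list.
#' @return Validated configuration list of class `ims_run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(names(config)))
    stop("config must be a named list or a YAML file path", call. = FALSE)
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$workflow) ||
      !config$workflow %in% c("stepped", "single", "twims"))
    stop("config 'workflow' must be one of: stepped, single, twims",
         call. = FALSE)
  for (key in names(.config_defaults)) {
    if (is.null(config[[key]])) config[[key]] <- .config_defaults[[key]]
  }
  if (config$tolerance_ppm <= 0) stop("tolerance_ppm must be positive",
                                      call. = FALSE)
  if (config$r2_threshold <= 0 || config$r2_threshold > 1)
    stop("r2_threshold must be in (0, 1]", call. = FALSE)
  structure(config, class = "ims_run_config")
}

.load_features <- function(path) {
  if (grepl("\\.cef$", path, ignore.case = TRUE)) read_features_cef(path)
  else read_features_csv(path)
}

.config_gas <- function(config) {
  if (!is.null(config$gas_mass)) buffer_gas(config$gas, mass = config$gas_mass)
  else buffer_gas(config$gas)
}

#' Run a complete CCS workflow
#'
#' Dispatches on `config$workflow`:
#' \describe{
#'   \item{stepped}{reads features + frame metadata + target list, runs
#'     the stepped-field combination search and writes one result row per
#'     passing conformer plus replicate statistics.}
#'   \item{single}{reads features (multiple runs keyed by `run_id`) +
#'     per-run metadata + calibrant list, fits one linear calibration per
#'     calibrant run (runs whose id matches `calibrant_run_pattern`),
#'     assigns each sample run its following-closest same-polarity
#'     calibration, and calibrates all sample features untargeted.}
#'   \item{twims}{reads calibrant-run features + calibrant list, fits the
#'     polynomial (`mode: polynomial`) or linearized power
#'     (`mode: power`) calibration and applies it to all features.}
#' }
#' Artifacts written to `out_dir`: `results.tsv` (tab-delimited CCS
#' records), `calibration_<run>.json` per fitted calibration,
#' `report.txt`, and (if `plots: true`) diagnostic PDF plots. Plot
#' failures degrade to warnings. Identical inputs produce byte-identical
#' result tables.
#'
#' @param config A configuration as accepted by [read_run_config()].
#' @return Invisibly, a list with the result records, fitted
#'   calibration(s) and output paths.
#' @export
run_workflow <- function(config) {
  config <- read_run_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config 'out_dir' is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gas <- .config_gas(config)
  message("[imsccs] workflow=", config$workflow)
  res <- switch(config$workflow,
                stepped = .run_stepped(config, gas),
                single = .run_single(config, gas),
                twims = .run_twims(config, gas))
  results_path <- file.path(out_dir, "results.tsv")
  write_ccs_records(res$records, results_path)
  message("[imsccs] wrote ", nrow(res$records), " record(s) to ",
          results_path)
  for (nm in names(res$calibrations)) {
    write_calibration_json(res$calibrations[[nm]],
                           file.path(out_dir, paste0("calibration_", nm,
                                                     ".json")))
  }
  report_path <- file.path(out_dir, "report.txt")
  emit_report(res$records, res$calibrations, report_path)
  if (isTRUE(config$plots)) .emit_plots(res, out_dir)
  invisible(list(records = res$records, calibrations = res$calibrations,
                 results_path = results_path, report_path = report_path))
}

.run_stepped <- function(config, gas) {
  features <- .load_features(config$features)
  meta <- read_frame_metadata(config$metadata)
  targets <- read_targets_csv(config$targets)
  message("[imsccs] ", nrow(features), " features, ", nrow(meta),
          " fields, ", nrow(targets), " targets")
  runs <- unique(meta$run_id)
  all_recs <- list()
  for (r in runs) {
    fit <- fit_stepped_field(
      features[is.na(features$run_id) | features$run_id == r, , drop = FALSE],
      meta[meta$run_id == r, , drop = FALSE], targets,
      tol_ppm = config$tolerance_ppm, r2_threshold = config$r2_threshold,
      max_rank = config$max_rank,
      min_fields = config$min_fields, gas = gas)
    rec <- as.data.frame(fit)
    if (nrow(rec)) rec$run_id <- r
    all_recs[[r]] <- rec
  }
  recs <- ccs_records(do.call(rbind, all_recs))
  list(records = recs, calibrations = list(), stepped = NULL)
}

.run_single <- function(config, gas) {
  features <- .load_features(config$features)
  meta <- read_frame_metadata(config$metadata)
  calibrants <- read_calibrants_csv(config$calibrants)
  mode <- if (config$mode %in% c("standard", "enhanced", "tims_scan"))
    config$mode else "standard"
  cal_runs <- unique(meta$run_id[grepl(config$calibrant_run_pattern,
                                       meta$run_id)])
  if (!length(cal_runs))
    stop("no run_id matches calibrant_run_pattern '",
         config$calibrant_run_pattern, "'", call. = FALSE)
  message("[imsccs] ", length(cal_runs), " calibrant run(s), mode=", mode)
  calibrations <- list()
  for (r in cal_runs) {
    calibrations[[r]] <- fit_single_field(
      features[features$run_id == r, , drop = FALSE], calibrants,
      meta[meta$run_id == r, , drop = FALSE], mode = mode, gas = gas,
      tol_ppm = config$tolerance_ppm)
  }
  sample_runs <- setdiff(unique(meta$run_id), cal_runs)
  recs <- list()
  for (r in sample_runs) {
    cond <- meta[meta$run_id == r, , drop = FALSE]
    cal <- assign_calibration_run(cond, calibrations)
    recs[[r]] <- calibrate_features(
      features[features$run_id == r, , drop = FALSE], cal,
      conditions = cond, charge = config$charge)
  }
  records <- if (length(recs)) ccs_records(do.call(rbind, recs))
             else ccs_records(data.frame(name = character()))
  list(records = records, calibrations = calibrations)
}

.run_twims <- function(config, gas) {
  features <- .load_features(config$features)
  calibrants <- read_calibrants_csv(config$calibrants)
  method <- if (identical(config$mode, "power")) "power" else "polynomial"
  message("[imsccs] TWIMS ", method, " calibration, t_acc=", config$t_acc,
          " edc=", config$edc)
  cal_features <- if (any(grepl(config$calibrant_run_pattern,
                                features$run_id)))
    features[grepl(config$calibrant_run_pattern, features$run_id), ,
             drop = FALSE]
  else features
  cal <- if (method == "power")
    fit_twims_power(cal_features, calibrants, gas = gas, edc = config$edc,
                    t_acc = config$t_acc, tol_ppm = config$tolerance_ppm)
  else
    fit_twims_poly(cal_features, calibrants, gas = gas,
                   degree = config$degree, t_acc = config$t_acc,
                   tol_ppm = config$tolerance_ppm)
  records <- apply_twims_calibration(features, cal, charge = config$charge)
  list(records = records, calibrations = list(twims = cal))
}

#' Emit a deterministic workflow report
#'
#' Plain-text summary of record counts, per-molecule replicate statistics
#' (mean CCS and percent RSD), flag tallies and calibration coefficients.
#' The report contains no timestamps, so identical inputs produce
#' byte-identical reports.
#'
#' @param records A [ccs_records()] data frame.
#' @param calibrations Optional named list of `ccs_cal` objects.
#' @param path Output path; `NULL` returns the lines invisibly without
#'   writing.
#' @return The report lines, invisibly.
#' @export
emit_report <- function(records, calibrations = NULL, path = NULL) {
  lines <- c("imsccs workflow report",
             "======================",
             sprintf("records: %d", nrow(records)))
  if (nrow(records) == 0L) {
    lines <- c(lines, "zero results")
  } else {
    with_ccs <- sum(!is.na(records$ccs))
    lines <- c(lines, sprintf("records with CCS: %d", with_ccs))
    flags <- unlist(strsplit(records$flags[nzchar(records$flags)], ";",
                             fixed = TRUE))
    if (length(flags)) {
      tab <- sort(table(flags), decreasing = TRUE)
      lines <- c(lines, "flags:",
                 sprintf("  %s: %d", names(tab), as.integer(tab)))
    }
    named <- records[!is.na(records$name) & !is.na(records$ccs), ,
                     drop = FALSE]
    if (nrow(named)) {
      stats <- summarize_replicates(named)
      lines <- c(lines, "replicate statistics (mean CCS, %RSD):",
                 sprintf("  %s %s: n=%d mean=%.4f rsd=%.2f%%%s",
                         stats$name, ifelse(is.na(stats$adduct), "",
                                            stats$adduct),
                         stats$n, stats$mean_ccs, stats$rsd_pct,
                         ifelse(nzchar(stats$flags),
                                paste0(" [", stats$flags, "]"), "")))
    }
  }
  if (length(calibrations)) {
    lines <- c(lines, "calibrations:")
    for (nm in names(calibrations)) {
      cc <- calibrations[[nm]]
      lines <- c(lines, sprintf("  %s: mode=%s", nm, cc$mode))
    }
  }
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con)
  }
  invisible(lines)
}

.emit_plots <- function(res, out_dir) {
  tryCatch({
    for (nm in names(res$calibrations)) {
      grDevices::pdf(file.path(out_dir, paste0("calibration_", nm, ".pdf")))
      plot(res$calibrations[[nm]])
      grDevices::dev.off()
    }
  }, error = function(e) warning("plot generation failed: ",
                                 conditionMessage(e), call. = FALSE))
}
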