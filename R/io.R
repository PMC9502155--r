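# Readers and writers for the plain-text interchange formats: MZmine-style
# feature CSV, simplified CEF XML, frame-metadata CSV, target and calibrant
# lists, and the tab-delimited results table.
#
# Readers never reorder, deduplicate or filter rows; all selection logic
# lives downstream.

#' Column-name map for MZmine-style feature CSV
#'
#' MZmine exports label the arrival-time column "row retention time"
#' because arrival time is substituted for retention time when IMS frames
#' are converted to LC-MS-like files. The defaults follow the MZmine 2
#' export headers; override them for other dialects.
#'
#' @param mz Header of the m/z column.
#' @param arrival_time Header of the arrival-time column (values in ms).
#' @param intensity Header of the intensity column, or `NULL` to
#'   auto-detect: an exact `"intensity"` column, else the first header
#'   ending in "Peak height", else "Peak area".
#' @return A list of class `feature_dialect`.
#' @export
mzmine_dialect <- function(mz = "row m/z", arrival_time = "row retention time",
                           intensity = NULL) {
  structure(list(mz = mz, arrival_time = arrival_time, intensity = intensity),
            class = "feature_dialect")
}

.resolve_intensity_col <- function(headers, dialect) {
  if (!is.null(dialect$intensity)) {
    if (!dialect$intensity %in% headers)
      stop("feature table is missing required column '", dialect$intensity, "'",
           call. = FALSE)
    return(dialect$intensity)
  }
  lower <- tolower(headers)
  if ("intensity" %in% lower) return(headers[match("intensity", lower)])
  hit <- grep("peak height$", lower)
  if (length(hit)) return(headers[hit[1L]])
  hit <- grep("peak area$", lower)
  if (length(hit)) return(headers[hit[1L]])
  stop("feature table has no resolvable intensity column ",
       "(looked for 'intensity', '* Peak height', '* Peak area')", call. = FALSE)
}

.parse_numeric_col <- function(values, column) {
  out <- suppressWarnings(as.numeric(values))
  bad <- which(is.na(out) & !is.na(values) & nzchar(trimws(values)))
  if (length(bad))
    stop("unparseable numeric in column '", column, "' at data row ", bad[1L],
         call. = FALSE)
  out
}

# shared validation + classing for feature tables from any source
.as_features <- function(df) {
  stopifnot(all(c("mz", "arrival_time", "intensity") %in% names(df)))
  if (!"run_id" %in% names(df)) df$run_id <- rep(NA_character_, nrow(df))
  if (!"field_id" %in% names(df)) df$field_id <- rep(NA_integer_, nrow(df))
  if (any(!is.finite(df$mz)) || any(df$mz <= 0))
    stop("feature m/z values must be positive", call. = FALSE)
  if (any(!is.finite(df$arrival_time)) || any(df$arrival_time <= 0))
    stop("feature arrival times must be positive", call. = FALSE)
  if (any(!is.finite(df$intensity)) || any(df$intensity < 0))
    stop("feature intensities must be non-negative", call. = FALSE)
  core <- c("mz", "arrival_time", "intensity", "run_id", "field_id")
  df <- df[, c(core, setdiff(names(df), core)), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ims_features", "data.frame")
  df
}

#' Construct a feature table from vectors
#'
#' Validating constructor used by the synthetic generators and available
#' for programmatic input. Extra columns are carried through untouched.
#'
#' @param mz m/z values (Th), positive.
#' @param arrival_time Arrival times (ms), positive.
#' @param intensity Intensities (counts), non-negative.
#' @param run_id,field_id Optional run label and stepped-field index.
#' @param ... Further equal-length columns to carry through.
#' @return A data frame of class `ims_features`.
#' @export
ims_features <- function(mz, arrival_time, intensity, run_id = NA_character_,
                         field_id = NA_integer_, ...) {
  .as_features(data.frame(mz = mz, arrival_time = arrival_time,
                          intensity = intensity, run_id = run_id,
                          field_id = field_id, ...,
                          stringsAsFactors = FALSE, check.names = FALSE))
}

#' Read an MZmine-style feature CSV
#'
#' @param path Path to the CSV file.
#' @param dialect A [mzmine_dialect()] column-name map.
#' @param run_id Run label to attach when the file does not carry a
#'   `run_id` column.
#' @return A data frame of class `ims_features` with columns `mz`,
#'   `arrival_time` (ms), `intensity`, `run_id`, `field_id` and any
#'   unrecognised columns passed through. Row order is preserved.
#' @export
read_features_csv <- function(path, dialect = mzmine_dialect(), run_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  for (col in c("mz", "arrival_time")) {
    if (!dialect[[col]] %in% names(raw))
      stop("feature table is missing required column '", dialect[[col]], "'",
           call. = FALSE)
  }
  int_col <- .resolve_intensity_col(names(raw), dialect)
  used <- c(dialect$mz, dialect$arrival_time, int_col)
  df <- data.frame(
    mz = .parse_numeric_col(raw[[dialect$mz]], dialect$mz),
    arrival_time = .parse_numeric_col(raw[[dialect$arrival_time]],
                                      dialect$arrival_time),
    intensity = .parse_numeric_col(raw[[int_col]], int_col),
    stringsAsFactors = FALSE)
  if ("run_id" %in% names(raw)) {
    df$run_id <- raw[["run_id"]]
    used <- c(used, "run_id")
  } else df$run_id <- if (is.null(run_id)) NA_character_ else run_id
  if ("field_id" %in% names(raw)) {
    df$field_id <- as.integer(.parse_numeric_col(raw[["field_id"]], "field_id"))
    used <- c(used, "field_id")
  }
  if ("charge_z" %in% names(raw)) {
    df$charge_z <- as.integer(.parse_numeric_col(raw[["charge_z"]], "charge_z"))
    used <- c(used, "charge_z")
  }
  extra <- setdiff(names(raw), used)
  for (col in extra) df[[col]] <- raw[[col]]
  .as_features(df)
}

#' Write an MZmine-style feature CSV
#'
#' Companion writer to [read_features_csv()], used by the synthetic
#' generators; emits the default MZmine 2 headers.
#'
#' @param features An `ims_features` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  out <- data.frame(`row m/z` = features$mz,
                    `row retention time` = features$arrival_time,
                    intensity = features$intensity,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(is.na(features$run_id))) out$run_id <- features$run_id
  if (!all(is.na(features$field_id))) out$field_id <- features$field_id
  if ("charge_z" %in% names(features)) out$charge_z <- features$charge_z
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simplified CEF XML feature file
#'
#' Parses the minimal CEF dialect this package defines: a `CEF` root with
#' a `CompoundList` of `Compound` elements, each carrying a `Location`
#' element with attributes `m` (m/z), `dt` (drift/arrival time, ms) and
#' `y` (intensity). Full vendor CEF is out of scope.
#'
#' @param path Path to the XML file.
#' @param run_id Optional run label to attach.
#' @return A data frame of class `ims_features`.
#' @export
read_features_cef <- function(path, run_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  compounds <- xml2::xml_find_all(doc, ".//Compound")
  if (length(compounds) == 0L)
    return(.as_features(data.frame(mz = numeric(), arrival_time = numeric(),
                                   intensity = numeric())))
  loc <- lapply(compounds, function(cp) {
    node <- xml2::xml_find_first(cp, "./Location")
    if (inherits(node, "xml_missing"))
      stop("CEF Compound without Location element", call. = FALSE)
    m <- xml2::xml_attr(node, "m")
    dt <- xml2::xml_attr(node, "dt")
    y <- xml2::xml_attr(node, "y")
    if (is.na(dt))
      stop("CEF Location missing drift-time attribute 'dt'", call. = FALSE)
    if (is.na(m))
      stop("CEF Location missing m/z attribute 'm'", call. = FALSE)
    c(m = as.numeric(m), dt = as.numeric(dt),
      y = if (is.na(y)) 0 else as.numeric(y))
  })
  mat <- do.call(rbind, loc)
  .as_features(data.frame(mz = mat[, "m"], arrival_time = mat[, "dt"],
                          intensity = mat[, "y"],
                          run_id = if (is.null(run_id)) NA_character_ else run_id,
                          stringsAsFactors = FALSE))
}

#' Write a simplified CEF XML feature file
#'
#' @param features An `ims_features` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_cef <- function(features, path) {
  doc <- xml2::xml_new_root("CEF", version = "1.0")
  lst <- xml2::xml_add_child(doc, "CompoundList")
  for (i in seq_len(nrow(features))) {
    cp <- xml2::xml_add_child(lst, "Compound")
    xml2::xml_add_child(cp, "Location",
                        m = format(features$mz[i], digits = 15),
                        dt = format(features$arrival_time[i], digits = 15),
                        y = format(features$intensity[i], digits = 15))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.parse_timestamp <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  ts <- as.POSIXct(x, tz = "UTC", tryFormats = c("%Y-%m-%d %H:%M:%OS",
                                                 "%Y-%m-%d %H:%M"))
  if (any(is.na(ts))) stop("unparseable timestamp: ",
                           x[which(is.na(ts))[1L]], call. = FALSE)
  ts
}

# shared validation + classing for frame metadata
.as_frame_meta <- function(df) {
  need <- c("run_id", "field_id", "voltage_V", "pressure_Torr",
            "temperature_C", "length_cm", "timestamp", "polarity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("frame metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$field_id <- as.integer(df$field_id)
  key <- paste(df$run_id, df$field_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (run_id, field_id) in frame metadata: ",
         sub("\r", "/", key[duplicated(key)][1L]), call. = FALSE)
  if (any(df$voltage_V <= 0) || any(df$pressure_Torr <= 0) ||
      any(df$length_cm <= 0))
    stop("voltage, pressure and drift length must be positive", call. = FALSE)
  if (any(df$temperature_C <= -273.15))
    stop("temperature below absolute zero", call. = FALSE)
  if (!all(df$polarity %in% c("positive", "negative")))
    stop("polarity must be 'positive' or 'negative'", call. = FALSE)
  df$timestamp <- .parse_timestamp(as.character(df$timestamp))
  rownames(df) <- NULL
  class(df) <- c("ims_frame_meta", "data.frame")
  df
}

#' Read a frame-metadata CSV
#'
#' Per-field (stepped-field) or per-run (single-field) instrument
#' conditions: drift voltage, drift-gas pressure and temperature, drift
#' length, acquisition timestamp and polarity. One record per
#' (run_id, field_id); duplicates are rejected.
#'
#' @param path CSV with columns `run_id`, `field_id`, `voltage_V`,
#'   `pressure_Torr`, `temperature_C`, `length_cm`, `timestamp`
#'   (ISO-8601; naive timestamps are taken as UTC), `polarity`.
#' @return A data frame of class `ims_frame_meta`.
#' @export
read_frame_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  .as_frame_meta(df)
}

#' Frame temperatures in Kelvin
#'
#' @param meta An `ims_frame_meta` data frame (temperatures stored in
#'   Celsius at the I/O boundary).
#' @return Numeric vector of temperatures in K.
#' @export
frame_temperature_K <- function(meta) celsius_to_kelvin(meta$temperature_C)

#' Read a target-molecule list
#'
#' @param path CSV with columns `name` and `neutral_mass` (Da).
#' @return A data frame with validated, uniquely named targets.
#' @export
read_targets_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "neutral_mass") %in% names(df)))
    stop("target list needs columns 'name' and 'neutral_mass'", call. = FALSE)
  if (anyDuplicated(df$name))
    stop("duplicate target name: ", df$name[duplicated(df$name)][1L],
         call. = FALSE)
  if (any(df$neutral_mass <= 0)) stop("neutral masses must be positive",
                                      call. = FALSE)
  df
}

#' Read a calibrant-ion list
#'
#' @param path CSV with columns `name`, `mz` (Th), `z` (charge), `ccs`
#'   (reference CCS, square Angstroms) and `polarity`.
#' @return A validated data frame of calibrant ions.
#' @export
read_calibrants_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "mz", "z", "ccs", "polarity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("calibrant list missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$mz <= 0) || any(df$ccs <= 0))
    stop("calibrant mz and ccs must be positive", call. = FALSE)
  df$z <- as.integer(df$z)
  df
}

# canonical result-table columns, in output order
.ccs_record_cols <- c("name", "adduct", "mz", "charge_z", "ccs", "K0",
                      "r_squared", "n_fields", "intensity", "mass_error_ppm",
                      "arrival_time", "flags")

#' Construct a CCS result table
#'
#' Fills any missing canonical columns with `NA` and validates ranges.
#' `flags` is a `;`-separated string per row (possibly empty) drawn from
#' `extrapolated`, `low_fields`, `duplicate_conformer`, `invalid`,
#' `single_replicate`, `fallback_calibration`.
#'
#' @param df A data frame with a subset of the canonical columns.
#' @return A data frame of class `ccs_records` in canonical column order.
#' @export
ccs_records <- function(df) {
  for (col in .ccs_record_cols) {
    if (!col %in% names(df)) {
      fill <- if (col %in% c("name", "adduct", "flags")) NA_character_
              else NA_real_
      df[[col]] <- rep(fill, nrow(df))
    }
  }
  if (!all(is.na(df$ccs)) && any(df$ccs[!is.na(df$ccs)] <= 0))
    stop("ccs must be positive where present", call. = FALSE)
  r2 <- df$r_squared[!is.na(df$r_squared)]
  if (length(r2) && (any(r2 < 0) || any(r2 > 1 + 1e-12)))
    stop("r_squared must lie in [0, 1]", call. = FALSE)
  df$flags[is.na(df$flags)] <- ""
  df <- df[, c(.ccs_record_cols, setdiff(names(df), .ccs_record_cols)),
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ccs_records", "data.frame")
  df
}

#' Write a CCS result table
#'
#' Tab-delimited, fixed column order, rows sorted by name, adduct then
#' m/z, CCS and K0 printed with 4 decimal places. The ordering and
#' formatting are deterministic so identical inputs yield byte-identical
#' files.
#'
#' @param records A [ccs_records()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ccs_records <- function(records, path) {
  records <- ccs_records(records)
  ord <- order(records$name, records$adduct, records$mz, method = "radix")
  records <- records[ord, .ccs_record_cols, drop = FALSE]
  fmt4 <- function(x) ifelse(is.na(x), "", sprintf("%.4f", x))
  out <- data.frame(
    name = records$name, adduct = records$adduct,
    mz = ifelse(is.na(records$mz), "", sprintf("%.4f", records$mz)),
    charge_z = records$charge_z, ccs = fmt4(records$ccs),
    K0 = fmt4(records$K0),
    r_squared = ifelse(is.na(records$r_squared), "",
                       sprintf("%.6f", records$r_squared)),
    n_fields = records$n_fields,
    intensity = ifelse(is.na(records$intensity), "",
                       format(records$intensity, digits = 10, trim = TRUE,
                              scientific = FALSE)),
    mass_error_ppm = ifelse(is.na(records$mass_error_ppm), "",
                            sprintf("%.3f", records$mass_error_ppm)),
    arrival_time = fmt4(records$arrival_time), flags = records$flags,
    stringsAsFactors = FALSE, check.names = FALSE)
  con <- file(path, open = "wb")  # binary mode: fixed \n line endings
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", eol = "\n")
  invisible(path)
}

#' Read back a CCS result table
#'
#' @param path A file written by [write_ccs_records()].
#' @return A `ccs_records` data frame (numeric within printed precision).
#' @export
read_ccs_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  num <- c("mz", "charge_z", "ccs", "K0", "r_squared", "n_fields",
           "intensity", "mass_error_ppm", "arrival_time")
  for (col in num) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  df$flags[is.na(df$flags)] <- ""
  ccs_records(df)
}
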