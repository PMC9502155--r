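# Shared in-code fixtures: tune-mix style calibrant ions with literature
# reference CCS in nitrogen, a TAA-like helium calibrant ladder, and small
# target sets. All campaigns are generated at test time by the synth_*
# generators.

tunemix_calibrants <- function() {
  data.frame(
    name = c("TuneMix322", "TuneMix622", "TuneMix922", "TuneMix1222",
             "TuneMix1522"),
    mz = c(322.0481, 622.0290, 922.0098, 1221.9906, 1521.9715),
    z = 1L,
    ccs = c(153.7, 203.0, 243.6, 282.2, 317.0),
    polarity = "positive",
    stringsAsFactors = FALSE)
}

# tetraalkylammonium-style ladder for helium TWIMS calibrations
# (synthetic reference values, single charge)
taa_calibrants <- function() {
  data.frame(
    name = paste0("TAA", c(4, 5, 6, 7, 8)),
    mz = c(130.1590, 186.2216, 242.2842, 298.3468, 354.4094),
    z = 1L,
    ccs = c(80.1, 102.5, 123.6, 143.8, 162.9),
    polarity = "positive",
    stringsAsFactors = FALSE)
}

tunemix_targets <- function() {
  cal <- tunemix_calibrants()
  data.frame(name = cal$name, neutral_mass = cal$mz - 1.007276466,
             stringsAsFactors = FALSE)
}

tunemix_ions <- function() {
  cal <- tunemix_calibrants()
  data.frame(name = cal$name, mz = cal$mz, charge_z = cal$z, ccs = cal$ccs,
             polarity = cal$polarity, stringsAsFactors = FALSE)
}

# deterministic frame-metadata builder for unit tests
make_meta <- function(voltages = seq(850, 1450, by = 100), P = 3.95,
                      T_C = 28, L = 78.24, run_id = "run1",
                      polarity = "positive") {
  n <- length(voltages)
  df <- data.frame(
    run_id = run_id, field_id = seq_len(n), voltage_V = voltages,
    pressure_Torr = P, temperature_C = T_C, length_cm = L,
    timestamp = format(as.POSIXct("2024-03-01 08:00:00", tz = "UTC") +
                         60 * (seq_len(n) - 1L), "%Y-%m-%dT%H:%M:%S"),
    polarity = polarity, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  read_frame_metadata(path)
}
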