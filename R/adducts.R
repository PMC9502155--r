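# Adduct-ion generation from neutral target masses and m/z tolerance
# matching against feature tables.

.proton_mass <- 1.007276466  # Da, H+ (proton)
.sodium_ion_mass <- 22.989218  # Da, Na+ (Na minus one electron)

#' Default adduct table
#'
#' Protonated forms up to 4+, sodiated 1+, and deprotonated 1- ions.
#' Users can extend or replace the table; `label` must be unique.
#'
#' @return Data frame with columns `label`, `mass_shift` (Da),
#'   `charge_z`, `polarity`.
#' @export
default_adducts <- function() {
  data.frame(
    label = c("[M+H]+", "[M+2H]2+", "[M+3H]3+", "[M+4H]4+", "[M+Na]+",
              "[M-H]-"),
    mass_shift = c(.proton_mass, 2 * .proton_mass, 3 * .proton_mass,
                   4 * .proton_mass, .sodium_ion_mass, -.proton_mass),
    charge_z = c(1L, 2L, 3L, 4L, 1L, 1L),
    polarity = c("positive", "positive", "positive", "positive", "positive",
                 "negative"),
    stringsAsFactors = FALSE)
}

#' Generate target ions from neutral masses and adducts
#'
#' Takes the Cartesian product of target molecules and adduct
#' specifications (optionally restricted to one polarity) and computes the
#' expected m/z `(neutral_mass + mass_shift) / charge_z` and the ion mass
#' of each adduct ion.
#'
#' @param targets Data frame with `name` and `neutral_mass` (Da), as read
#'   by [read_targets_csv()].
#' @param adducts Adduct table as from [default_adducts()].
#' @param polarity Optional `"positive"`/`"negative"` filter (the run
#'   polarity); `NULL` keeps all adducts.
#' @return Data frame with one row per (molecule, adduct): `name`,
#'   `adduct`, `polarity`, `charge_z`, `expected_mz`, `ion_mass`.
#' @export
#' @examples
#' targets <- data.frame(name = "d-Biotin", neutral_mass = 244.0882)
#' generate_target_ions(targets, polarity = "positive")
generate_target_ions <- function(targets, adducts = default_adducts(),
                                 polarity = NULL) {
  if (nrow(adducts) == 0L) stop("adduct table is empty", call. = FALSE)
  if (anyDuplicated(adducts$label))
    stop("adduct labels must be unique", call. = FALSE)
  if (any(adducts$charge_z < 1))
    stop("adduct charge must be >= 1", call. = FALSE)
  if (!is.null(polarity)) {
    polarity <- match.arg(polarity, c("positive", "negative"))
    adducts <- adducts[adducts$polarity == polarity, , drop = FALSE]
  }
  if (nrow(targets) == 0L || nrow(adducts) == 0L)
    return(data.frame(name = character(), adduct = character(),
                      polarity = character(), charge_z = integer(),
                      expected_mz = numeric(), ion_mass = numeric(),
                      stringsAsFactors = FALSE))
  grid <- expand.grid(t = seq_len(nrow(targets)), a = seq_len(nrow(adducts)))
  out <- data.frame(
    name = targets$name[grid$t],
    adduct = adducts$label[grid$a],
    polarity = adducts$polarity[grid$a],
    charge_z = adducts$charge_z[grid$a],
    stringsAsFactors = FALSE)
  out$expected_mz <- (targets$neutral_mass[grid$t] +
                        adducts$mass_shift[grid$a]) / out$charge_z
  out$ion_mass <- .ion_mass(out$expected_mz, out$charge_z, out$polarity)
  # stable, deterministic order: molecules as given, adducts as given
  out <- out[order(grid$t, grid$a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match features to an expected m/z within a ppm tolerance
#'
#' @param features An `ims_features` data frame.
#' @param expected_mz Expected m/z of the target ion (Th).
#' @param tol_ppm m/z tolerance in parts per million (default 20).
#' @return The matching subset of `features` with a `mass_error_ppm`
#'   column, sorted by descending intensity (ties: ascending arrival
#'   time, then ascending m/z).
#' @export
match_features <- function(features, expected_mz, tol_ppm = 20) {
  if (!is.numeric(tol_ppm) || tol_ppm <= 0)
    stop("tol_ppm must be positive", call. = FALSE)
  ppm <- (features$mz - expected_mz) / expected_mz * 1e6
  keep <- abs(ppm) <= tol_ppm
  out <- features[keep, , drop = FALSE]
  out$mass_error_ppm <- ppm[keep]
  ord <- order(-out$intensity, out$arrival_time, out$mz, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only the most intense features
#'
#' Limits a candidate list to the top `max_rank` features by intensity,
#' the rank limit that keeps the stepped-field combination search
#' tractable. Intensity ties are broken by ascending arrival time, then
#' ascending m/z, so the selection is deterministic.
#'
#' @param features An `ims_features` data frame.
#' @param max_rank Number of features to keep (>= 1).
#' @return The top-ranked subset, in rank order.
#' @export
limit_by_intensity_rank <- function(features, max_rank) {
  if (!is.numeric(max_rank) || max_rank < 1)
    stop("max_rank must be >= 1", call. = FALSE)
  ord <- order(-features$intensity, features$arrival_time, features$mz,
               method = "radix")
  out <- features[ord[seq_len(min(max_rank, nrow(features)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}
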