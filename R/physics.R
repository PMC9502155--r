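# Physical constants and closed-form mobility/CCS conversions shared by all
# calibration modes.

.ims_const <- list(
  boltzmann_k       = 1.380649e-23,   # J/K (exact, SI 2019)
  elementary_charge = 1.602176634e-19, # C (exact, SI 2019)
  loschmidt_N0      = 2.6867801e25,   # molecules/m^3 at 273.15 K, 760 Torr
  amu_to_kg         = 1.66053906660e-27,
  electron_mass_Da  = 5.48579909e-4,
  standard_T        = 273.15,         # K
  standard_P        = 760             # Torr
)

#' Physical constants used in mobility/CCS conversions
#'
#' Returns the pinned CODATA constants the package uses everywhere: the
#' Boltzmann constant (J/K), the elementary charge (C), the Loschmidt
#' constant (buffer-gas number density at 273.15 K and 760 Torr, m^-3),
#' the unified atomic mass unit in kg, the electron mass in Da, and the
#' standard temperature (K) and pressure (Torr) of the reduced-mobility
#' reference state.
#'
#' @return A named list of constants. The list is a copy; the internal
#'   table cannot be modified.
#' @export
#' @examples
#' ims_constants()$boltzmann_k
ims_constants <- function() .ims_const

#' Buffer gas descriptor
#'
#' Builds a buffer-gas object carrying the gas name and its average
#' molecular mass in Da. Nitrogen and helium are built in; any other gas
#' can be supplied by giving `mass` explicitly.
#'
#' @param name Gas name. `"nitrogen"`/`"N2"` and `"helium"`/`"He"` are
#'   recognised (case-insensitive); anything else requires `mass`.
#' @param mass Molecular mass in Da, overriding the built-in table.
#' @return An object of class `buffer_gas` with elements `name` and `mass`.
#' @export
#' @examples
#' buffer_gas("N2")$mass    # 28.0134
#' buffer_gas("helium")
buffer_gas <- function(name = "nitrogen", mass = NULL) {
  known <- c(nitrogen = 28.0134, n2 = 28.0134, helium = 4.002602, he = 4.002602)
  key <- tolower(name)
  if (is.null(mass)) {
    if (!key %in% names(known))
      stop("unknown buffer gas '", name, "'; supply `mass` in Da", call. = FALSE)
    mass <- unname(known[[key]])
  }
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0)
    stop("buffer gas mass must be a single positive number (Da)", call. = FALSE)
  structure(list(name = as.character(name), mass = mass), class = "buffer_gas")
}

#' @export
print.buffer_gas <- function(x, ...) {
  cat(sprintf("<buffer_gas> %s (%.6f Da)\n", x$name, x$mass))
  invisible(x)
}

#' Ion species descriptor
#'
#' Describes a measured ion by its m/z, charge state and polarity. The ion
#' mass is derived as `mz * z` minus (positive mode) or plus (negative
#' mode) `z` electron masses, so that the neutral/ion mass bookkeeping is
#' deterministic even though the correction is far below typical mass
#' accuracy.
#'
#' @param mz Mass-to-charge ratio (Th), positive.
#' @param charge_z Integer charge state, >= 1.
#' @param polarity `"positive"` or `"negative"`.
#' @return An object of class `ion_species` with fields `mz`, `charge_z`,
#'   `ion_mass` (Da) and `polarity`.
#' @export
#' @examples
#' ion_species(322.0481, 1)
ion_species <- function(mz, charge_z = 1L, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(mz) || length(mz) != 1L || !is.finite(mz) || mz <= 0)
    stop("mz must be a single positive number", call. = FALSE)
  if (!is.numeric(charge_z) || length(charge_z) != 1L || charge_z < 1 ||
      charge_z != round(charge_z))
    stop("charge_z must be a positive integer", call. = FALSE)
  charge_z <- as.integer(charge_z)
  ion_mass <- .ion_mass(mz, charge_z, polarity)
  structure(list(mz = mz, charge_z = charge_z, ion_mass = ion_mass,
                 polarity = polarity),
            class = "ion_species")
}

# vectorised ion-mass rule: electrons removed in positive mode, added in
# negative mode
.ion_mass <- function(mz, z, polarity) {
  sgn <- ifelse(polarity == "negative", 1, -1)
  mz * z + sgn * z * .ims_const$electron_mass_Da
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion_species> m/z %.4f, z=%d (%s), ion mass %.4f Da\n",
              x$mz, x$charge_z, x$polarity, x$ion_mass))
  invisible(x)
}

#' Convert Celsius to Kelvin
#'
#' @param temperature_C Temperature in degrees Celsius.
#' @return Temperature in K.
#' @export
celsius_to_kelvin <- function(temperature_C) {
  if (any(!is.finite(temperature_C)) || any(temperature_C <= -273.15))
    stop("temperature must be finite and above absolute zero", call. = FALSE)
  temperature_C + 273.15
}

#' Reduced mass of an ion/buffer-gas pair
#'
#' @param ion_mass Ion mass in Da (> 0). Vectorised.
#' @param gas_mass Buffer-gas mass in Da (> 0).
#' @return Reduced mass `ion_mass * gas_mass / (ion_mass + gas_mass)` in Da.
#' @export
#' @examples
#' reduced_mass(322.0481, 28.0134)
reduced_mass <- function(ion_mass, gas_mass) {
  if (any(!is.finite(ion_mass)) || any(ion_mass <= 0) ||
      any(!is.finite(gas_mass)) || any(gas_mass <= 0))
    stop("masses must be positive and finite", call. = FALSE)
  ion_mass * gas_mass / (ion_mass + gas_mass)
}

# Mason-Schamp prefactor in SI for one ion: 3 z e / (16 N0) * sqrt(2 pi /
# (mu k T)), with mu converted from Da to kg. Multiplying by 1/K0 (m^2/Vs)
# gives the CCS in m^2.
.ms_prefactor <- function(z, ion_mass, gas_mass, T_K) {
  mu_kg <- reduced_mass(ion_mass, gas_mass) * .ims_const$amu_to_kg
  3 * z * .ims_const$elementary_charge / (16 * .ims_const$loschmidt_N0) *
    sqrt(2 * pi / (mu_kg * .ims_const$boltzmann_k * T_K))
}

#' Collision cross section from reduced mobility
#'
#' Evaluates the low-field Mason-Schamp relation: the CCS is proportional
#' to the ionic charge and to `1/K0`, with the thermal factor
#' `sqrt(2*pi / (mu * k * T))` computed from the ion/buffer-gas reduced
#' mass.
#'
#' @param K0 Reduced mobility in cm^2/(V s), positive. Vectorised.
#' @param ion An [ion_species()] object (or list with `charge_z` and
#'   `ion_mass`).
#' @param gas A [buffer_gas()] object.
#' @param T_K Drift-gas temperature in K, positive.
#' @return CCS in square Angstroms.
#' @seealso [ccs_to_mobility()] for the exact algebraic inverse.
#' @export
#' @examples
#' ion <- ion_species(322.0481, 1)
#' mobility_to_ccs(1.38, ion, buffer_gas("N2"), T_K = 301.15)
mobility_to_ccs <- function(K0, ion, gas = buffer_gas("nitrogen"), T_K) {
  if (any(!is.finite(K0)) || any(K0 <= 0))
    stop("K0 must be positive", call. = FALSE)
  if (!is.finite(T_K) || T_K <= 0)
    stop("temperature must be positive (K)", call. = FALSE)
  pref <- .ms_prefactor(ion$charge_z, ion$ion_mass, gas$mass, T_K)
  # K0 cm^2/Vs -> m^2/Vs (1e-4); result m^2 -> Angstrom^2 (1e20)
  pref / (K0 * 1e-4) * 1e20
}

#' Reduced mobility from collision cross section
#'
#' Algebraic inverse of [mobility_to_ccs()].
#'
#' @param ccs CCS in square Angstroms, positive. Vectorised.
#' @inheritParams mobility_to_ccs
#' @return Reduced mobility K0 in cm^2/(V s).
#' @export
ccs_to_mobility <- function(ccs, ion, gas = buffer_gas("nitrogen"), T_K) {
  if (any(!is.finite(ccs)) || any(ccs <= 0))
    stop("ccs must be positive", call. = FALSE)
  if (!is.finite(T_K) || T_K <= 0)
    stop("temperature must be positive (K)", call. = FALSE)
  pref <- .ms_prefactor(ion$charge_z, ion$ion_mass, gas$mass, T_K)
  pref / (ccs * 1e-20) * 1e4
}

# mass/charge scaling that takes a CCS to its reduced form:
# sqrt(mI/(mI+mB)) / z. Vectorised over ion_mass and z.
.reduced_ccs_factor <- function(z, ion_mass, gas_mass) {
  sqrt(ion_mass / (ion_mass + gas_mass)) / z
}

#' Reduced collision cross section
#'
#' Scales a CCS by `sqrt(mI / (mI + mB)) / z` so that calibrant ions of
#' different mass and charge fall on a single calibration curve. This is
#' the x-axis quantity of the standard single-field calibration.
#'
#' @param ccs CCS in square Angstroms, positive. Vectorised.
#' @param ion An [ion_species()] object.
#' @param gas A [buffer_gas()] object.
#' @return Reduced CCS (same numeric scale as `ccs`, scaled down).
#' @export
reduced_ccs <- function(ccs, ion, gas = buffer_gas("nitrogen")) {
  if (any(!is.finite(ccs)) || any(ccs <= 0))
    stop("ccs must be positive", call. = FALSE)
  ccs * .reduced_ccs_factor(ion$charge_z, ion$ion_mass, gas$mass)
}

#' Invert a reduced collision cross section
#'
#' @param ccs_reduced Reduced CCS as produced by [reduced_ccs()].
#' @inheritParams reduced_ccs
#' @return The original CCS in square Angstroms.
#' @export
reduced_ccs_inverse <- function(ccs_reduced, ion, gas = buffer_gas("nitrogen")) {
  if (any(!is.finite(ccs_reduced)) || any(ccs_reduced <= 0))
    stop("reduced ccs must be positive", call. = FALSE)
  ccs_reduced / .reduced_ccs_factor(ion$charge_z, ion$ion_mass, gas$mass)
}

#' Pressure/temperature-adjusted reduced CCS
#'
#' Multiplies the reduced CCS by `P/T`, the per-run correction of the
#' enhanced single-field calibration. With this x-axis the calibration
#' absorbs drift in drift-gas pressure and temperature between the
#' calibrant run and each sample run.
#'
#' @inheritParams reduced_ccs
#' @param P Drift-gas pressure in Torr, positive.
#' @param T_K Drift-gas temperature in K, positive.
#' @return Adjusted reduced CCS (`P/T` times the reduced CCS).
#' @export
adjusted_reduced_ccs <- function(ccs, ion, gas = buffer_gas("nitrogen"), P, T_K) {
  if (!is.finite(P) || P <= 0) stop("pressure must be positive (Torr)", call. = FALSE)
  if (!is.finite(T_K) || T_K <= 0) stop("temperature must be positive (K)", call. = FALSE)
  (P / T_K) * reduced_ccs(ccs, ion, gas)
}
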