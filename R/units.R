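#' @keywords internal
"_PACKAGE"

# Molar gas constant, J/(mol K)
R_GAS <- 8.31446261815324

#' Convert a v/v dilution to a liquid-phase molar concentration
#'
#' A source prepared as a volume fraction of pure odorant in solvent (e.g.
#' "0.1%" = 1e-3 v/v) is converted to mol/m^3 using the odorant's density
#' and molecular weight. Linear in the volume fraction, as appropriate for
#' infinite dilution.
#'
#' @param fraction_vv Volume fraction of odorant in the solvent, in `[0, 1]`.
#' @param compound A [compound()] with `mw` and `density` set.
#' @return Liquid concentration in mol/m^3.
#' @examples
#' z3ha <- compound("Z3HA", khl = 2.71e-5, mw = 142.2, density = 0.897)
#' dilution_to_liquid_molar(1e-3, z3ha)  # ~6.31 mol/m^3
#' @export
dilution_to_liquid_molar <- function(fraction_vv, compound) {
  stopifnot(inherits(compound, "compound"))
  if (any(!is.finite(fraction_vv)) || any(fraction_vv < 0) ||
      any(fraction_vv > 1)) {
    stop("'fraction_vv' must lie in [0, 1]", call. = FALSE)
  }
  for (field in c("mw", "density")) {
    if (is.null(compound[[field]])) {
      stop(sprintf("missing physical constants: compound '%s' has no '%s'",
                   compound$name, field), call. = FALSE)
    }
  }
  # density g/mL -> g/m^3 is *1e6; mol/m^3 = g/m^3 / (g/mol)
  fraction_vv * compound$density * 1e6 / compound$mw
}

#' Headspace concentration at thermodynamic equilibrium (Henry's law)
#'
#' At infinite dilution the equilibrium headspace concentration is
#' proportional to the liquid concentration, `Ch0 = Khl * Cl0`.
#'
#' @param cl0 Liquid concentration, mol/m^3 (>= 0).
#' @param khl Dimensionless air-solvent partition coefficient (> 0), or a
#'   [compound()].
#' @return Equilibrium headspace concentration, mol/m^3.
#' @export
henry_headspace <- function(cl0, khl) {
  khl <- as_khl(khl)
  if (any(!is.finite(cl0)) || any(cl0 < 0)) {
    stop("'cl0' must be non-negative", call. = FALSE)
  }
  if (khl <= 0) stop("'khl' must be positive", call. = FALSE)
  khl * cl0
}

# Accept either a bare numeric Khl or a compound object.
as_khl <- function(khl) {
  if (inherits(khl, "compound")) khl$khl else as.numeric(khl)
}

#' Convert a gas-phase molar concentration to a ppbv mixing ratio
#'
#' Uses the ideal gas law: the mixing ratio is the odorant molar
#' concentration divided by the total molar density of air `P/(R T)`.
#'
#' @param c_gas Gas-phase concentration, mol/m^3 (>= 0).
#' @param air An [air_properties()] object supplying temperature and pressure.
#' @return Mixing ratio in parts per billion by volume.
#' @examples
#' molar_to_ppbv(41.3e-9, air_properties())  # ~1 ppbv
#' @export
molar_to_ppbv <- function(c_gas, air = air_properties()) {
  stopifnot(inherits(air, "air_properties"))
  if (any(!is.finite(c_gas)) || any(c_gas < 0)) {
    stop("'c_gas' must be non-negative", call. = FALSE)
  }
  c_gas * R_GAS * air$temperature / air$pressure * 1e9
}

#' @rdname molar_to_ppbv
#' @param ppbv Mixing ratio in parts per billion by volume.
#' @export
ppbv_to_molar <- function(ppbv, air = air_properties()) {
  stopifnot(inherits(air, "air_properties"))
  if (any(!is.finite(ppbv)) || any(ppbv < 0)) {
    stop("'ppbv' must be non-negative", call. = FALSE)
  }
  ppbv * 1e-9 * air$pressure / (R_GAS * air$temperature)
}

#' Amount of pure odorant needed to reach a target headspace concentration
#'
#' Mass balance over a closed two-phase bottle at equilibrium: the loaded
#' amount partitions between headspace (at the target concentration) and
#' solvent (at target/Khl).
#'
#' @param c_target_headspace Desired equilibrium headspace concentration,
#'   mol/m^3.
#' @param v_solvent Solvent volume, m^3 (> 0).
#' @param v_headspace Headspace volume, m^3 (> 0).
#' @param compound A [compound()] or a bare positive `khl` value.
#' @return Amount of odorant to load, mol.
#' @export
bottle_loading <- function(c_target_headspace, v_solvent, v_headspace,
                           compound) {
  khl <- as_khl(compound)
  if (!is.finite(khl) || khl <= 0) {
    stop("'khl' must be strictly positive: no equilibrium solution otherwise",
         call. = FALSE)
  }
  stopifnot(v_solvent > 0, v_headspace > 0)
  if (any(!is.finite(c_target_headspace)) || any(c_target_headspace < 0)) {
    stop("'c_target_headspace' must be non-negative", call. = FALSE)
  }
  c_target_headspace * v_headspace + (c_target_headspace / khl) * v_solvent
}

#' Small unit helpers for the interface layer
#'
#' Internally everything is SI (m, s, mol, m^3, Pa, K); these helpers convert
#' the bench units in which devices are usually described.
#'
#' @param x Numeric value(s) in the source unit.
#' @return Value(s) in SI units (m^3, m^3/s, m, or m^2).
#' @name units
NULL

#' @rdname units
#' @export
ml_to_m3 <- function(x) x * 1e-6

#' @rdname units
#' @export
ml_min_to_m3_s <- function(x) x * 1e-6 / 60

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
cm2_to_m2 <- function(x) x * 1e-4
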