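# Physical constants (CODATA 2018) and unit conversions.
# All internal computation is in atomic units; conversion happens at I/O edges.

#' Physical constants and derived conversion factors
#'
#' Returns the package unit registry: CODATA 2018 fundamental constants plus
#' the derived conversion factors used throughout (dipole a.u. to Debye,
#' hartree to cm^-1, beta a.u. to SI, IR intensity and Raman activity unit
#' chains). Every derived factor is computed from the fundamental constants
#' at call time, never hard-coded, so the registry doubles as its own
#' consistency check.
#'
#' @return A named list of constants. Fundamental entries carry SI values;
#'   `*_factor` entries are dimensionless conversion multipliers.
#' @examples
#' uc <- unit_constants()
#' uc$beta_au_si      # 1 a.u. of beta in C^3 m^3 J^-2 (approx 3.206361e-53)
#' uc$dipole_au_debye # 1 a.u. of dipole in Debye (approx 2.5417)
#' @export
unit_constants <- function() {
  e   <- 1.602176634e-19        # elementary charge, C (exact)
  a0  <- 0.529177210903e-10     # Bohr radius, m
  Eh  <- 4.3597447222071e-18    # Hartree energy, J
  h   <- 6.62607015e-34         # Planck constant, J s (exact)
  c0  <- 2.99792458e8           # speed of light, m/s (exact)
  NA_ <- 6.02214076e23          # Avogadro constant, 1/mol (exact)
  eps0 <- 8.8541878128e-12      # vacuum permittivity, F/m
  me  <- 9.1093837015e-31       # electron mass, kg
  amu <- 1.66053906660e-27      # unified atomic mass unit, kg

  debye <- 1e-21 / c0           # 1 D in C m (3.33564e-30)
  ang   <- 1e-10                # 1 Angstrom in m

  # derivative unit chains for double-harmonic intensities
  me_amu <- me / amu                       # electron mass in amu
  dmu_au_to_DAamu  <- (e * a0 / debye) / ((a0 / ang) * sqrt(me_amu))
  dalpha_au_to_A2amu <- (a0 / ang)^2 / sqrt(me_amu)

  # IR intensity: I[km/mol] = K * (dmu/dQ)^2; K = N_A/(12 eps0 c^2) in the
  # (D, Angstrom, amu) chain, then rescaled to other derivative conventions.
  K_ir_si <- NA_ / (12 * eps0 * c0^2)                   # m/mol per (C/sqrt(kg))^2 ... SI chain
  K_ir_DAamu <- K_ir_si * (debye / (ang * sqrt(amu)))^2 / 1000  # km/mol
  K_ir_eamu  <- K_ir_DAamu * (e * ang / debye)^2                # derivatives in e/sqrt(amu)
  K_ir_au    <- K_ir_DAamu * dmu_au_to_DAamu^2                  # derivatives in full a.u.

  list(
    e = e, a0 = a0, Eh = Eh, h = h, c = c0, N_A = NA_, eps0 = eps0,
    me = me, amu = amu, debye = debye,
    dipole_au_debye   = e * a0 / debye,
    bohr_angstrom     = a0 / ang,
    hartree_cm1       = Eh / (h * c0) / 100,
    hartree_joule     = Eh,
    beta_au_si        = e^3 * a0^3 / Eh^2,
    dmu_au_to_DAamu   = dmu_au_to_DAamu,
    dalpha_au_to_A2amu = dalpha_au_to_A2amu,
    K_ir_DAamu = K_ir_DAamu,
    K_ir_eamu  = K_ir_eamu,
    K_ir_au    = K_ir_au
  )
}

.unit_pairs <- function() {
  uc <- unit_constants()
  # kind -> from -> to -> multiplicative factor
  list(
    dipole = list(
      au    = c(debye = uc$dipole_au_debye),
      debye = c(au = 1 / uc$dipole_au_debye)
    ),
    energy = list(
      hartree = c(cm1 = uc$hartree_cm1, joule = uc$hartree_joule),
      cm1     = c(hartree = 1 / uc$hartree_cm1,
                  joule = uc$hartree_joule / uc$hartree_cm1),
      joule   = c(hartree = 1 / uc$hartree_joule,
                  cm1 = uc$hartree_cm1 / uc$hartree_joule)
    ),
    beta = list(
      au = c(si = uc$beta_au_si),
      si = c(au = 1 / uc$beta_au_si)
    ),
    length = list(
      bohr     = c(angstrom = uc$bohr_angstrom),
      angstrom = c(bohr = 1 / uc$bohr_angstrom)
    )
  )
}

#' Convert a scalar between registered units
#'
#' Linear unit conversion for the quantity kinds used by the package:
#' `"dipole"` (au, debye), `"energy"` (hartree, cm1, joule), `"beta"`
#' (au, si) and `"length"` (bohr, angstrom). Round-trip conversion is the
#' identity to machine precision.
#'
#' @param value Numeric scalar or vector.
#' @param kind Quantity kind, one of `"dipole"`, `"energy"`, `"beta"`,
#'   `"length"`.
#' @param from,to Unit names registered for `kind`.
#' @return Converted numeric value(s).
#' @examples
#' convert_units(1, "beta", "au", "si")       # 3.206361e-53
#' convert_units(1, "energy", "hartree", "cm1")
#' @export
convert_units <- function(value, kind, from, to) {
  pairs <- .unit_pairs()
  if (!kind %in% names(pairs))
    stop("unknown quantity kind: ", kind, call. = FALSE)
  if (from == to) return(value)
  tab <- pairs[[kind]]
  if (!from %in% names(tab) || !to %in% names(tab[[from]]))
    stop("unknown unit pair for ", kind, ": ", from, " -> ", to, call. = FALSE)
  value * unname(tab[[from]][to])
}

#' Percent change relative to a reference
#'
#' @param reference Nonzero reference value.
#' @param value New value.
#' @return `100 * (value - reference) / reference`.
#' @examples
#' percent_change(123.0, 254.9)  # +107.2 (solvent enhancement of beta_vec)
#' @export
percent_change <- function(reference, value) {
  if (any(reference == 0)) stop("percent_change: zero reference", call. = FALSE)
  100 * (value - reference) / reference
}
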