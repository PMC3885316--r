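# Double-harmonic pure vibrational first-order hyperpolarizability:
# the [mu alpha]^(0,0) square-bracket term, its infinite-frequency EOPE/SHG
# limits, per-mode contributions, and double-harmonic IR/Raman intensities.
#
# Derivative convention: d(mu)/dQ and d(alpha)/dQ are stored in pure atomic
# units per mass-weighted normal coordinate (bohr * sqrt(m_e)); wavenumbers
# in cm^-1 are converted to hartree internally before squaring, the only
# reading that returns beta in a.u.

#' Normal mode with property derivatives
#'
#' @param index 1-based mode index (matching "nu_25"-style labels).
#' @param wavenumber Harmonic wavenumber, cm^-1; must be > 0 for modes
#'   entering the vibrational beta sum (no imaginary modes).
#' @param dmu Length-3 dipole derivative d(mu_i)/dQ, a.u.
#' @param dalpha 3x3 symmetric polarizability derivative d(alpha_jk)/dQ, a.u.
#' @param label Free-text description (e.g. "nu C=O + delta N-H").
#' @return Object of class `normal_mode`.
#' @export
normal_mode <- function(index, wavenumber, dmu, dalpha, label = "") {
  dmu <- as.numeric(dmu); stopifnot(length(dmu) == 3)
  dalpha <- matrix(as.numeric(dalpha), 3, 3)
  if (max(abs(dalpha - t(dalpha))) > 1e-8 * max(abs(dalpha), 1))
    stop("normal_mode: dalpha must be symmetric", call. = FALSE)
  structure(list(index = as.integer(index), wavenumber = as.numeric(wavenumber),
                 dmu = dmu, dalpha = (dalpha + t(dalpha)) / 2,
                 label = as.character(label)),
            class = "normal_mode")
}

.check_modes <- function(modes, floor_cm1) {
  for (m in modes) {
    if (!inherits(m, "normal_mode")) stop("expected a list of normal_mode objects",
                                          call. = FALSE)
    if (m$wavenumber <= 0)
      stop("mode ", m$index, ": non-positive wavenumber ", m$wavenumber,
           " cm^-1 cannot enter the double-harmonic sum", call. = FALSE)
  }
  Filter(function(m) m$wavenumber >= floor_cm1, modes)
}

.bracket_one <- function(m) {
  w_au <- convert_units(m$wavenumber, "energy", "cm1", "hartree")
  b <- array(0, c(3, 3, 3))
  dmu <- m$dmu; da <- m$dalpha
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    b[i, j, k] <- dmu[i] * da[j, k] + dmu[j] * da[i, k] + dmu[k] * da[i, j]
  b / w_au^2
}

#' Double-harmonic square-bracket term \[mu alpha\]^(0,0)
#'
#' Sums over normal modes
#' `(dmu_i dalpha_jk + dmu_j dalpha_ik + dmu_k dalpha_ij) / omega_a^2`
#' with the harmonic wavenumber converted to hartree before squaring.
#' This is the static pure vibrational beta in the double-harmonic
#' approximation; additive over modes.
#'
#' Translations and rotations are excluded by a wavenumber floor: only the
#' 3N-6 genuine vibrations belong in the sum.
#'
#' @param modes List of [normal_mode()] objects.
#' @param floor_cm1 Modes below this wavenumber are excluded (default 50).
#' @return 3x3x3 array (Kleinman-symmetric by construction of the formula),
#'   atomic units.
#' @export
mu_alpha_bracket <- function(modes, floor_cm1 = 50) {
  modes <- .check_modes(modes, floor_cm1)
  out <- array(0, c(3, 3, 3))
  for (m in modes) out <- out + .bracket_one(m)
  out
}

#' Vibrational beta for an NLO process (infinite-frequency limit)
#'
#' In the infinite optical frequency limit the pure vibrational beta is
#' `(1/3) [mu alpha]^(0,0)` for the electro-optic Pockels effect
#' (EOPE, `beta(-w; w, 0)`) and vanishes identically for second harmonic
#' generation (SHG, `beta(-2w; w, w)`).
#'
#' @param bracket A [mu_alpha_bracket()] array.
#' @param process `"EOPE"`, `"SHG"`, or `"static"` (the bracket itself).
#' @return A [beta_tensor()] (Kleinman symmetry).
#' @export
beta_v_process <- function(bracket, process = c("EOPE", "SHG", "static")) {
  process <- match.arg(process)
  arr <- switch(process,
                EOPE = bracket / 3,
                SHG = array(0, c(3, 3, 3)),
                static = bracket)
  beta_tensor(arr, symmetry = "kleinman")
}

#' Per-mode vibrational beta_vec contributions
#'
#' Evaluates each mode's single-term square-bracket tensor, applies the
#' process limit, and reports that mode's `beta_vec` together with its IR
#' intensity and Raman activity. Per-mode `beta_vec` values are norms of
#' per-mode vectors: they do NOT sum to the total `beta_vec`, which must be
#' computed from the summed tensor (vector composition allows
#' cancellation).
#'
#' @inheritParams mu_alpha_bracket
#' @param process Passed to [beta_v_process()].
#' @return data.frame with columns `index`, `wavenumber`, `beta_vec`,
#'   `I_IR` (km/mol), `A_Raman` (A^4/amu), `label`.
#' @export
per_mode_beta_vec <- function(modes, process = "EOPE", floor_cm1 = 50) {
  modes <- .check_modes(modes, floor_cm1)
  rows <- lapply(modes, function(m) {
    bv <- beta_vec(beta_v_process(.bracket_one(m), process))
    data.frame(index = m$index, wavenumber = m$wavenumber, beta_vec = bv,
               I_IR = ir_intensity(m), A_Raman = raman_activity(m),
               label = m$label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Double-harmonic IR intensity of a mode
#'
#' `I_IR = K * |dmu/dQ|^2` with the standard double-harmonic constant
#' `K = N_A / (12 eps0 c^2)`, which evaluates to 42.2561 km/mol for
#' derivatives in D A^-1 amu^-1/2 (equivalently 974.8802 for e amu^-1/2).
#' Derivatives stored in pure a.u. are converted internally.
#'
#' @param mode A [normal_mode()].
#' @return Intensity in km/mol; zero iff the dipole derivative is zero.
#' @export
ir_intensity <- function(mode) {
  uc <- unit_constants()
  uc$K_ir_au * sum(mode$dmu^2)
}

#' Double-harmonic Raman scattering activity of a mode
#'
#' `A = 45 a'^2 + 7 g'^2` from the isotropic invariant
#' `a' = tr(dalpha/dQ)/3` and anisotropy
#' `g'^2 = (1/2)[(axx-ayy)^2 + (ayy-azz)^2 + (azz-axx)^2] +
#' 3(axy^2 + ayz^2 + azx^2)`, with derivatives converted from a.u. to
#' A^2 amu^-1/2 so the activity comes out in the customary A^4/amu.
#'
#' @param mode A [normal_mode()].
#' @return Activity in A^4/amu.
#' @export
raman_activity <- function(mode) {
  uc <- unit_constants()
  da <- mode$dalpha * uc$dalpha_au_to_A2amu
  iso <- sum(diag(da)) / 3
  aniso2 <- 0.5 * ((da[1, 1] - da[2, 2])^2 + (da[2, 2] - da[3, 3])^2 +
                   (da[3, 3] - da[1, 1])^2) +
    3 * (da[1, 2]^2 + da[2, 3]^2 + da[1, 3]^2)
  45 * iso^2 + 7 * aniso2
}
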