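# Lorentzian IR/Raman spectral simulation and frequency-dispersion /
# solvent-ratio analysis of beta_vec series.

#' Stick spectrum
#'
#' @param position Peak positions, cm^-1.
#' @param intensity Non-negative stick intensities (km/mol for IR,
#'   A^4/amu for Raman activities).
#' @param kind `"IR"` or `"Raman"`.
#' @param phase Phase label, e.g. `"gas"` or `"water"`.
#' @return Object of class `stick_spectrum`.
#' @export
stick_spectrum <- function(position, intensity, kind = c("IR", "Raman"),
                           phase = "gas") {
  kind <- match.arg(kind)
  position <- as.numeric(position); intensity <- as.numeric(intensity)
  stopifnot(length(position) == length(intensity))
  if (any(intensity < 0)) stop("stick_spectrum: negative intensity", call. = FALSE)
  structure(list(position = position, intensity = intensity, kind = kind,
                 phase = phase),
            class = "stick_spectrum")
}

#' Lorentzian broadening of a stick spectrum
#'
#' Sums area-normalized Lorentzians centred on each stick and scaled by its
#' intensity, so the integral over an isolated peak equals the stick
#' intensity (area convention, chosen so integrated band strengths track
#' I_IR / A_Raman). The peak height of a single stick of intensity I is
#' `2 I / (pi * fwhm)`.
#'
#' @param sticks A [stick_spectrum()].
#' @param fwhm Full width at half maximum, cm^-1 (default 10).
#' @param grid Wavenumber grid (cm^-1) on which to evaluate.
#' @return data.frame with columns `wavenumber`, `intensity`.
#' @export
broaden <- function(sticks, fwhm = 10, grid = seq(0, 4000, by = 1)) {
  stopifnot(inherits(sticks, "stick_spectrum"), fwhm > 0)
  g <- as.numeric(grid)
  y <- numeric(length(g))
  hw <- fwhm / 2
  for (i in seq_along(sticks$position))
    y <- y + sticks$intensity[i] * (hw / pi) / ((g - sticks$position[i])^2 + hw^2)
  data.frame(wavenumber = g, intensity = y)
}

#' Frequency-dispersion series of beta_vec values
#'
#' An ordered table of `(hbar omega, beta_vec)` samples for one NLO process
#' and phase, anchored at the static value (`hw = 0`). The physically
#' relevant range here is 0-0.06563 a.u. (the upper end is the ruby-laser
#' wavelength, 694 nm); no extrapolation beyond the sampled range is ever
#' performed.
#'
#' @param hw Photon energies, a.u.; non-negative, strictly increasing, must
#'   contain 0.
#' @param beta_vec beta_vec values, a.u.
#' @param process `"static"`, `"EOPE"` or `"SHG"`.
#' @param phase Phase label (`"gas"`, `"water"`).
#' @return Object of class `dispersion_series`.
#' @export
dispersion_series <- function(hw, beta_vec, process = c("static", "EOPE", "SHG"),
                              phase = "gas") {
  process <- match.arg(process)
  hw <- as.numeric(hw); beta_vec <- as.numeric(beta_vec)
  stopifnot(length(hw) == length(beta_vec), length(hw) >= 1)
  if (any(hw < 0)) stop("dispersion_series: negative photon energy", call. = FALSE)
  if (is.unsorted(hw, strictly = TRUE))
    stop("dispersion_series: hw must be strictly increasing", call. = FALSE)
  if (min(hw) != 0)
    stop("dispersion_series: static anchor hw = 0 is required", call. = FALSE)
  structure(list(hw = hw, beta_vec = beta_vec, process = process, phase = phase),
            class = "dispersion_series")
}

.series_at <- function(series, hw) {
  i <- which(abs(series$hw - hw) < 1e-12)
  if (length(i)) return(series$beta_vec[i[1]])
  if (hw < min(series$hw) || hw > max(series$hw))
    stop("hw = ", hw, " outside the sampled range [", min(series$hw), ", ",
         max(series$hw), "] a.u.", call. = FALSE)
  series$beta_vec[which.min(abs(series$hw - hw))]   # nearest sample, no extrapolation
}

#' Dispersion effect at a photon energy, as a percentage of the static value
#'
#' @param series A [dispersion_series()].
#' @param hw Photon energy (a.u.) within the sampled range; nearest-sample
#'   lookup with exact-match preference.
#' @return `percent_change(beta_vec(0), beta_vec(hw))`.
#' @export
dispersion_percent <- function(series, hw) {
  percent_change(.series_at(series, 0), .series_at(series, hw))
}

#' Solvent enhancement ratio between two dispersion series
#'
#' @param water,gas [dispersion_series()] objects with matching process
#'   tags.
#' @param hw Photon energy (a.u.) sampled in both.
#' @return `beta_vec_water(hw) / beta_vec_gas(hw)`.
#' @export
solvent_ratio <- function(water, gas, hw) {
  if (!identical(water$process, gas$process))
    stop("solvent_ratio: mismatched process tags (", water$process, " vs ",
         gas$process, ")", call. = FALSE)
  .series_at(water, hw) / .series_at(gas, hw)
}

#' Locate the first crossing of two dispersion series
#'
#' Linearly interpolates both series onto the union of their sample points
#' within the common range and returns the smallest photon energy at which
#' the sign of (a - b) changes, located by linear interpolation between the
#' bracketing samples. Returns `NA` if the difference never changes sign.
#'
#' @param a,b [dispersion_series()] objects with overlapping ranges.
#' @return Photon energy of the crossing (a.u.), or `NA_real_`.
#' @export
find_crossing <- function(a, b) {
  lo <- max(min(a$hw), min(b$hw)); hi <- min(max(a$hw), max(b$hw))
  if (lo >= hi) stop("find_crossing: no common sampled range", call. = FALSE)
  x <- sort(unique(c(a$hw[a$hw >= lo & a$hw <= hi], b$hw[b$hw >= lo & b$hw <= hi])))
  ya <- stats::approx(a$hw, a$beta_vec, xout = x)$y
  yb <- stats::approx(b$hw, b$beta_vec, xout = x)$y
  d <- ya - yb
  nz <- which(d != 0)
  if (length(nz) < 2) return(NA_real_)
  for (p in seq_len(length(nz) - 1)) {
    i <- nz[p]; j <- nz[p + 1]
    if (sign(d[i]) != sign(d[j])) {
      if (j > i + 1) return(x[i + 1])   # exact zero sampled between the lobes
      t <- d[i] / (d[i] - d[j])
      return(x[i] + t * (x[j] - x[i]))
    }
  }
  NA_real_
}

#' Vibrational-to-electronic beta ratio
#'
#' @param beta_v,beta_e Scalar beta_vec values (a.u.); `beta_e` nonzero.
#' @return `beta_v / beta_e`.
#' @examples
#' vib_electronic_ratio(65.0, 139.8)   # 0.46, gas phase EOPE at 694 nm
#' vib_electronic_ratio(193.9, 214.1)  # 0.91, aqueous phase
#' @export
vib_electronic_ratio <- function(beta_v, beta_e) {
  if (any(beta_e == 0)) stop("vib_electronic_ratio: zero electronic beta",
                             call. = FALSE)
  beta_v / beta_e
}
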