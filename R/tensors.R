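# Response-tensor types and rotational invariants.
#
# Index convention used everywhere in the package: beta_ijk means
# d^2 mu_i / dF_j dF_k at F = 0 in the Taylor expansion
#   mu_i(F) = mu_i(0) + alpha_ij F_j + (1/2!) beta_ijk F_j F_k
#             + (1/3!) gamma_ijkl F_j F_k F_l
# so the 1/2! of the expansion cancels against the second-derivative factor
# and stored beta components ARE the Taylor coefficients. gamma likewise.

.AXES <- c(x = 1L, y = 2L, z = 3L)

.axis_index <- function(a) {
  if (is.character(a)) {
    i <- .AXES[tolower(a)]
    if (any(is.na(i))) stop("unknown axis: ", paste(a, collapse = ","), call. = FALSE)
    unname(i)
  } else as.integer(a)
}

# ---- Dipole ----------------------------------------------------------------

#' Dipole moment vector
#'
#' @param mu Numeric length-3 vector `(mu_x, mu_y, mu_z)`.
#' @param units `"au"` (default) or `"debye"`; stored as given, tagged.
#' @return Object of class `dipole`.
#' @examples
#' d <- dipole(c(1.21, 0, 4.41), units = "debye")
#' dipole_norm(d)  # 4.57 D, the gas-phase total dipole of uracil
#' @export
dipole <- function(mu, units = "au") {
  mu <- as.numeric(mu)
  stopifnot(length(mu) == 3, all(is.finite(mu)))
  units <- match.arg(units, c("au", "debye"))
  structure(list(mu = mu, units = units), class = "dipole")
}

#' Euclidean norm of a dipole
#' @param d A [dipole()].
#' @return Non-negative scalar in the dipole's own units.
#' @export
dipole_norm <- function(d) {
  stopifnot(inherits(d, "dipole"))
  sqrt(sum(d$mu^2))
}

#' @export
print.dipole <- function(x, ...) {
  cat(sprintf("<dipole> (%s): [%g, %g, %g], |mu| = %g\n",
              x$units, x$mu[1], x$mu[2], x$mu[3], dipole_norm(x)))
  invisible(x)
}

# ---- Alpha -----------------------------------------------------------------

#' Polarizability tensor (3x3, symmetric)
#'
#' @param mat 3x3 numeric matrix in atomic units.
#' @param tol Symmetry tolerance; the matrix is symmetrized and an error is
#'   raised if the asymmetry exceeds `tol` relative to the largest element.
#' @return Object of class `alpha_tensor`.
#' @export
alpha_tensor <- function(mat, tol = 1e-8) {
  mat <- matrix(as.numeric(mat), 3, 3)
  asym <- max(abs(mat - t(mat)))
  scale <- max(abs(mat), 1)
  if (asym > tol * scale)
    stop("alpha_tensor: matrix not symmetric within tolerance", call. = FALSE)
  structure(list(a = (mat + t(mat)) / 2), class = "alpha_tensor")
}

# ---- Beta ------------------------------------------------------------------

.symmetrize_jk <- function(arr) {
  (arr + aperm(arr, c(1, 3, 2))) / 2
}

.symmetrize_kleinman <- function(arr) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- array(0, c(3, 3, 3))
  for (p in perms) out <- out + aperm(arr, p)
  out / length(perms)
}

#' First-order hyperpolarizability tensor (3x3x3)
#'
#' The tensor is symmetrized on construction according to the declared index
#' symmetry: `"kleinman"` (all permutations of ijk; appropriate for static
#' beta far from resonance, the default) or `"jk"` (last two indices only;
#' what a finite-field extraction of d^2 mu_i/dF_j dF_k yields).
#'
#' @param arr 3x3x3 numeric array, atomic units.
#' @param symmetry `"kleinman"` or `"jk"`.
#' @return Object of class `beta_tensor` with fields `b` (array) and
#'   `symmetry`.
#' @seealso [beta_from_components()] to build from named `beta_ijj`-style
#'   values, [beta_components()], [beta_vec()].
#' @export
beta_tensor <- function(arr, symmetry = c("kleinman", "jk")) {
  symmetry <- match.arg(symmetry)
  arr <- array(as.numeric(arr), c(3, 3, 3))
  b <- if (symmetry == "kleinman") .symmetrize_kleinman(arr) else .symmetrize_jk(arr)
  structure(list(b = b, symmetry = symmetry), class = "beta_tensor")
}

#' Build a beta tensor from named components
#'
#' Components are named by axis triplets, e.g. `zxx` for beta_zxx. Each
#' value is assigned to every index permutation of its name (the form in
#' which static beta tables are printed), after which the declared symmetry
#' is enforced.
#'
#' @param components Named numeric vector or list, names like `"xxx"`,
#'   `"zxx"`.
#' @param symmetry Passed to [beta_tensor()].
#' @return A `beta_tensor`.
#' @examples
#' # gas-phase static beta of uracil from its printed z-row components:
#' b <- beta_from_components(c(zxx = -106.5, zyy = -36.5, zzz = 78.2))
#' beta_components(b)["z"]  # -64.8 a.u.
#' @export
beta_from_components <- function(components, symmetry = "kleinman") {
  arr <- array(0, c(3, 3, 3))
  comp <- as.list(components)
  for (nm in names(comp)) {
    idx <- .axis_index(strsplit(nm, "")[[1]])
    if (length(idx) != 3) stop("bad component name: ", nm, call. = FALSE)
    v <- as.numeric(comp[[nm]])
    perms <- unique(list(idx, idx[c(1, 3, 2)], idx[c(2, 1, 3)],
                         idx[c(2, 3, 1)], idx[c(3, 1, 2)], idx[c(3, 2, 1)]))
    for (p in perms) arr[p[1], p[2], p[3]] <- v
  }
  beta_tensor(arr, symmetry = symmetry)
}

#' Contracted beta components beta_i
#'
#' `beta_i = (1/3) sum_j (beta_ijj + beta_jij + beta_jji)`; under Kleinman
#' symmetry this reduces to `sum_j beta_ijj`. These are the vector
#' components entering the `beta_vec` invariant.
#'
#' @param beta A `beta_tensor` (or raw 3x3x3 array).
#' @return Named numeric 3-vector `(x, y, z)`.
#' @export
beta_components <- function(beta) {
  b <- if (inherits(beta, "beta_tensor")) beta$b else array(as.numeric(beta), c(3, 3, 3))
  out <- numeric(3)
  for (i in 1:3) {
    s <- 0
    for (j in 1:3) s <- s + b[i, j, j] + b[j, i, j] + b[j, j, i]
    out[i] <- s / 3
  }
  names(out) <- names(.AXES)
  out
}

#' Rotational invariant beta_vec
#'
#' `beta_vec = sqrt(beta_x^2 + beta_y^2 + beta_z^2)` with `beta_i` from
#' [beta_components()]. Invariant under rotation of the molecular frame.
#'
#' @param beta A `beta_tensor` or raw 3x3x3 array.
#' @return Non-negative scalar (a.u.).
#' @export
beta_vec <- function(beta) {
  sqrt(sum(beta_components(beta)^2))
}

#' @export
print.beta_tensor <- function(x, ...) {
  bc <- beta_components(x)
  cat(sprintf("<beta_tensor> symmetry=%s  beta_x=%.4g beta_y=%.4g beta_z=%.4g  beta_vec=%.4g\n",
              x$symmetry, bc[1], bc[2], bc[3], beta_vec(x)))
  invisible(x)
}

#' Rotate a beta tensor
#'
#' Applies an orthogonal rotation `R` to all three indices:
#' `beta'_ijk = R_ia R_jb R_kc beta_abc`.
#'
#' @param beta A `beta_tensor`.
#' @param R 3x3 rotation matrix.
#' @return Rotated `beta_tensor` with the same declared symmetry.
#' @export
rotate_beta <- function(beta, R) {
  stopifnot(inherits(beta, "beta_tensor"))
  R <- matrix(as.numeric(R), 3, 3)
  b <- beta$b
  out <- array(0, c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    s <- 0
    for (a in 1:3) for (bb in 1:3) for (cc in 1:3)
      s <- s + R[i, a] * R[j, bb] * R[k, cc] * b[a, bb, cc]
    out[i, j, k] <- s
  }
  structure(list(b = out, symmetry = beta$symmetry), class = "beta_tensor")
}

# ---- Gamma -----------------------------------------------------------------

#' Second-order hyperpolarizability tensor (3x3x3x3)
#'
#' Symmetrized over the last three indices on construction (the minimal
#' intrinsic symmetry of the Taylor coefficient d^3 mu_i/dF_j dF_k dF_l).
#'
#' @param arr 3x3x3x3 numeric array, atomic units.
#' @return Object of class `gamma_tensor`.
#' @export
gamma_tensor <- function(arr) {
  arr <- array(as.numeric(arr), c(3, 3, 3, 3))
  perms <- list(c(1, 2, 3, 4), c(1, 2, 4, 3), c(1, 3, 2, 4),
                c(1, 3, 4, 2), c(1, 4, 2, 3), c(1, 4, 3, 2))
  g <- array(0, c(3, 3, 3, 3))
  for (p in perms) g <- g + aperm(arr, p)
  structure(list(g = g / length(perms)), class = "gamma_tensor")
}
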