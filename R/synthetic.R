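# Synthetic model molecules with analytically known electronic and
# vibrational responses. These stand in for quantum-chemistry outputs in
# every test: a polynomial dipole surface with prescribed tensors, mode
# sets with prescribed derivatives, and Gaussian-blob densities whose
# field-shifted moments give beta in closed form.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Model molecule with prescribed response tensors
#'
#' @param mu0 Length-3 zero-field dipole (a.u.) or [dipole()].
#' @param alpha 3x3 polarizability (a.u.) or [alpha_tensor()].
#' @param beta 3x3x3 array or [beta_tensor()] (a.u.).
#' @param gamma 3x3x3x3 array or [gamma_tensor()] (a.u.).
#' @param modes Optional list of [normal_mode()] objects.
#' @param blobs Optional Gaussian-blob density model (see
#'   [gaussian_blob_model()]).
#' @param seed Optional integer recorded for provenance.
#' @return Object of class `model_molecule`.
#' @export
model_molecule <- function(mu0 = c(0, 0, 0), alpha = diag(3),
                           beta = array(0, c(3, 3, 3)),
                           gamma = array(0, rep(3, 4)),
                           modes = NULL, blobs = NULL, seed = NULL) {
  if (inherits(mu0, "dipole")) mu0 <- mu0$mu
  if (inherits(alpha, "alpha_tensor")) alpha <- alpha$a
  if (inherits(beta, "beta_tensor")) beta <- beta$b
  if (inherits(gamma, "gamma_tensor")) gamma <- gamma$g
  structure(list(mu0 = as.numeric(mu0), alpha = matrix(alpha, 3, 3),
                 beta = array(beta, c(3, 3, 3)), gamma = array(gamma, rep(3, 4)),
                 modes = modes, blobs = blobs, seed = seed),
            class = "model_molecule")
}

#' Exact polynomial dipole surface of a model molecule
#'
#' Returns a function of the applied field evaluating the induced-dipole
#' Taylor expansion exactly through the gamma term:
#' `mu(F) = mu0 + alpha F + (1/2) beta:FF + (1/6) gamma:FFF`.
#'
#' @param m A [model_molecule()].
#' @return Function `field 3-vector -> dipole 3-vector` (a.u.).
#' @export
make_dipole_surface <- function(m) {
  stopifnot(inherits(m, "model_molecule"))
  mu0 <- m$mu0; al <- m$alpha; be <- m$beta; ga <- m$gamma
  function(F) {
    F <- as.numeric(F)
    ff <- outer(F, F)
    quad <- vapply(1:3, function(i) sum(be[i, , ] * ff), numeric(1))
    fff <- outer(ff, F)
    cub <- vapply(1:3, function(i) sum(ga[i, , , ] * fff), numeric(1))
    as.numeric(mu0 + al %*% F + quad / 2 + cub / 6)
  }
}

#' Random model molecule with realistic response magnitudes
#'
#' Tensors are drawn at molecular scale: dipole of a few a.u.,
#' polarizability tens of a.u., beta magnitudes in the 10-300 a.u. decade
#' (the scale of static uracil-like beta components), gamma of order 10^3.
#'
#' @param seed Integer seed; generation is deterministic under it.
#' @return A [model_molecule()].
#' @export
random_model_molecule <- function(seed) {
  .with_seed(seed, {
    mu0 <- stats::runif(3, -2, 2)
    A <- matrix(stats::rnorm(9, sd = 3), 3, 3)
    alpha <- (A + t(A)) / 2 + diag(3) * 50
    bscale <- 10^stats::runif(1, 1, log10(300))
    beta <- .symmetrize_kleinman(array(stats::rnorm(27, sd = bscale), c(3, 3, 3)))
    gamma <- gamma_tensor(array(stats::rnorm(81, sd = 1000), rep(3, 4)))$g
    model_molecule(mu0, alpha, beta, gamma, seed = seed)
  })
}

#' Random synthetic mode set with recorded closed-form bracket
#'
#' Generates `n` normal modes with random dipole and (symmetric)
#' polarizability derivatives at prescribed scales, and records the
#' closed-form square-bracket tensor computed term by term at generation
#' time, for use as an oracle against [mu_alpha_bracket()].
#'
#' @param n Number of modes.
#' @param wavenumber_range Range (cm^-1) to draw wavenumbers from; default
#'   400-3700, the span of mid-IR fundamentals.
#' @param mu_scale,alpha_scale Gaussian scales of the derivative components
#'   (a.u.); defaults match the derivative magnitudes of intense mid-IR
#'   fundamentals (a ~900 km/mol carbonyl stretch has |dmu/dQ| ~ 0.02 a.u.,
#'   a ~60 A^4/amu Raman band |dalpha/dQ| ~ 0.2 a.u.).
#' @param seed Integer seed.
#' @return List with `modes` (list of [normal_mode()]) and `bracket`
#'   (3x3x3 array, the recorded \[mu alpha\]^(0,0)).
#' @export
make_mode_set <- function(n, wavenumber_range = c(400, 3700),
                          mu_scale = 0.02, alpha_scale = 0.2, seed = 1) {
  stopifnot(n >= 1)
  .with_seed(seed, {
    wn <- sort(stats::runif(n, wavenumber_range[1], wavenumber_range[2]))
    modes <- vector("list", n)
    bracket <- array(0, c(3, 3, 3))
    for (a in seq_len(n)) {
      dmu <- stats::rnorm(3, sd = mu_scale)
      S <- matrix(stats::rnorm(9, sd = alpha_scale), 3, 3)
      dalpha <- (S + t(S)) / 2
      modes[[a]] <- normal_mode(a, wn[a], dmu, dalpha, label = sprintf("synthetic mode %d", a))
      w2 <- (wn[a] / unit_constants()$hartree_cm1)^2
      for (i in 1:3) for (j in 1:3) for (k in 1:3)
        bracket[i, j, k] <- bracket[i, j, k] +
          (dmu[i] * dalpha[j, k] + dmu[j] * dalpha[i, k] + dmu[k] * dalpha[i, j]) / w2
    }
    list(modes = modes, bracket = bracket)
  })
}

# ---- Gaussian blob density models ------------------------------------------

#' Gaussian-blob density model with closed-form responses
#'
#' The charge density is a sum of normalized isotropic Gaussians whose
#' centres shift with the applied field,
#' `c(F) = c0 + a F + (1/2) b (F x F)`, so the analytic electronic dipole
#' `mu_i(F) = -sum_b q_b c_bi(F)` is an exact quadratic in F with
#' `mu0_i = -sum q c0_i`, `alpha_ij = -sum q a_ij` and
#' `beta_ijk = -sum q b_ijk` - an analytic beta with no electronic
#' structure theory involved.
#'
#' @param centers n x 3 matrix of zero-field blob centres (bohr).
#' @param charges Length-n positive charges (mock electron counts).
#' @param sigmas Length-n Gaussian widths (bohr; default 1.0).
#' @param a List of n 3x3 linear shift matrices (bohr per a.u. field).
#' @param b List of n 3x3x3 quadratic shift arrays, symmetric in the last
#'   two indices.
#' @return A [model_molecule()] whose tensors are the implied closed forms
#'   (gamma = 0) and whose `blobs` field drives [make_density_grids()].
#' @export
gaussian_blob_model <- function(centers, charges, sigmas = NULL, a = NULL, b = NULL) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  n <- nrow(centers)
  charges <- as.numeric(charges); stopifnot(length(charges) == n, all(charges > 0))
  if (is.null(sigmas)) sigmas <- rep(1.0, n)
  if (is.null(a)) a <- replicate(n, matrix(0, 3, 3), simplify = FALSE)
  if (is.null(b)) b <- replicate(n, array(0, c(3, 3, 3)), simplify = FALSE)
  b <- lapply(b, function(x) .symmetrize_jk(array(x, c(3, 3, 3))))
  mu0 <- -colSums(charges * centers)
  alpha <- matrix(0, 3, 3); beta <- array(0, c(3, 3, 3))
  for (q in seq_len(n)) {
    alpha <- alpha - charges[q] * matrix(a[[q]], 3, 3)
    beta <- beta - charges[q] * b[[q]]
  }
  blobs <- list(centers = centers, charges = charges, sigmas = as.numeric(sigmas),
                a = a, b = b)
  model_molecule(mu0, alpha, beta, gamma = array(0, rep(3, 4)), blobs = blobs)
}

#' Random Gaussian-blob model
#'
#' @param seed Integer seed.
#' @param nblob Number of blobs (default 3).
#' @return A [gaussian_blob_model()] with beta components of order 10-100
#'   a.u.
#' @export
random_blob_model <- function(seed, nblob = 3) {
  .with_seed(seed, {
    centers <- matrix(stats::runif(3 * nblob, -1.5, 1.5), ncol = 3)
    charges <- stats::runif(nblob, 1, 4)
    sigmas <- stats::runif(nblob, 0.8, 1.2)
    a <- replicate(nblob, {
      S <- matrix(stats::rnorm(9, sd = 0.5), 3, 3)
      (S + t(S)) / 2          # symmetric linear shifts -> symmetric implied alpha
    }, simplify = FALSE)
    b <- replicate(nblob, array(stats::rnorm(27, sd = 8), c(3, 3, 3)), simplify = FALSE)
    gaussian_blob_model(centers, charges, sigmas, a, b)
  })
}

.blob_center_at <- function(blobs, q, F) {
  bq <- blobs$b[[q]]
  quad <- vapply(1:3, function(i) sum(bq[i, , ] * outer(F, F)), numeric(1))
  blobs$centers[q, ] + as.numeric(matrix(blobs$a[[q]], 3, 3) %*% F) + quad / 2
}

#' Field-dependent density grids for a blob model
#'
#' Evaluates the blob density on a cubic grid centred at the origin for
#' every field in the stencil. Electron count is conserved analytically at
#' every field; on the grid it is conserved to quadrature tolerance. Errors
#' out if any blob (plus its maximal field shift) comes within `margin`
#' standard deviations of the box edge.
#'
#' @param m A model molecule with a `blobs` component.
#' @param stencil A [build_stencil()] (its fields tag the grids).
#' @param n Grid points per axis.
#' @param extent Half-width of the cubic box (bohr).
#' @param margin Required clearance in units of blob sigma (default 5).
#' @return List of [grid_density()] objects, one per stencil field.
#' @export
make_density_grids <- function(m, stencil, n = 64, extent = 8, margin = 5) {
  stopifnot(inherits(m, "model_molecule"))
  if (is.null(m$blobs)) stop("model molecule has no density (blob) model", call. = FALSE)
  blobs <- m$blobs
  fields <- stencil$fields
  # margin check over all fields and blobs
  for (q in seq_along(blobs$charges)) {
    reach <- 0
    for (r in seq_len(nrow(fields)))
      reach <- max(reach, max(abs(.blob_center_at(blobs, q, fields[r, ]))))
    if (reach + margin * blobs$sigmas[q] > extent)
      stop(sprintf("grid extent %.3g bohr too small: blob %d reaches %.3g + %g sigma",
                   extent, q, reach, margin), call. = FALSE)
  }
  spacing <- 2 * extent / (n - 1)
  x <- seq(-extent, extent, length.out = n)
  lapply(seq_len(nrow(fields)), function(r) {
    F <- fields[r, ]
    vals <- array(0, c(n, n, n))
    for (q in seq_along(blobs$charges)) {
      cc <- .blob_center_at(blobs, q, F)
      s2 <- blobs$sigmas[q]^2
      norm <- blobs$charges[q] * (2 * pi * s2)^(-1.5)
      ex <- exp(-(x - cc[1])^2 / (2 * s2))
      ey <- exp(-(x - cc[2])^2 / (2 * s2))
      ez <- exp(-(x - cc[3])^2 / (2 * s2))
      vals <- vals + norm * outer(outer(ex, ey), ez)
    }
    grid_density(origin = rep(-extent, 3), axes = diag(spacing, 3), values = vals,
                 field = F, title = "synthetic blob density")
  })
}
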