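# Hyperpolarizability-density analysis: second field-derivatives of gridded
# charge densities rho2_jk(r) and their first spatial moment, which yields
# beta_ijk. Grids are Gaussian-cube style: origin + integer combinations of
# three axis step vectors.

#' Gridded scalar density under an applied field
#'
#' @param origin Numeric 3-vector, bohr.
#' @param axes 3x3 matrix, rows = axis step vectors (bohr).
#' @param values Numeric array with dim = counts per axis; electrons/bohr^3.
#' @param field Applied-field tag, 3-vector in a.u.
#' @param atoms Optional data.frame (Z, charge, x, y, z) preserved on cube
#'   round-trip.
#' @param title Title string (cube line 1).
#' @return Object of class `grid_density`.
#' @export
grid_density <- function(origin, axes, values, field = c(0, 0, 0),
                         atoms = NULL, title = "density") {
  origin <- as.numeric(origin); stopifnot(length(origin) == 3)
  axes <- matrix(as.numeric(axes), 3, 3)
  if (abs(det(axes)) < 1e-14)
    stop("grid_density: axis vectors are linearly dependent", call. = FALSE)
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3)
  structure(list(origin = origin, axes = axes, counts = dim(values),
                 values = values, field = as.numeric(field),
                 atoms = atoms, title = title),
            class = "grid_density")
}

.cell_volume <- function(gd) abs(det(gd$axes))

#' Integrate a gridded density (midpoint/Riemann quadrature)
#' @param gd A `grid_density` or `hyper_density`.
#' @return Scalar integral `sum(values) * cell_volume`.
#' @export
grid_integral <- function(gd) sum(gd$values) * .cell_volume(gd)

.same_geometry <- function(a, b, tol = 1e-10) {
  all(abs(a$origin - b$origin) < tol) && all(abs(a$axes - b$axes) < tol) &&
    all(a$counts == b$counts)
}

# coordinates of grid points along cartesian component i (bohr)
.grid_coord <- function(gd, i) {
  n <- gd$counts
  ix <- slice.index(gd$values, 1) - 1L
  iy <- slice.index(gd$values, 2) - 1L
  iz <- slice.index(gd$values, 3) - 1L
  gd$origin[i] + ix * gd$axes[1, i] + iy * gd$axes[2, i] + iz * gd$axes[3, i]
}

.find_grid <- function(grids, field, tol = 1e-12) {
  for (g in grids) if (all(abs(g$field - field) < tol)) return(g)
  NULL
}

#' Hyperpolarizability density rho2_jk(r) from field-tagged grids
#'
#' Computes the pointwise second derivative of the charge density with
#' respect to two applied-field components at F = 0 by central differences:
#' for `j == k` from grids at fields `0, +-h e_j`; for `j != k` from the
#' 4-point cross `(+-h e_j +- h e_k)`. The field step h is auto-detected as
#' the smallest field magnitude present for the requested component pair
#' unless given.
#'
#' @param grids List of [grid_density()] objects sharing one geometry.
#' @param j,k Axis names or indices of the differentiated field components.
#' @param h Field step (a.u.); auto-detected when `NULL`.
#' @return Object of class `hyper_density` (same grid metadata, values =
#'   rho2, plus the component pair).
#' @export
rho2 <- function(grids, j, k, h = NULL) {
  j <- .axis_index(j); k <- .axis_index(k)
  stopifnot(length(grids) >= 2)
  g0 <- grids[[1]]
  for (g in grids) if (!.same_geometry(g0, g))
    stop("rho2: grids have mismatched geometry", call. = FALSE)
  uv <- function(a, s, hh) { v <- numeric(3); v[a] <- s * hh; v }
  if (is.null(h)) {
    mags <- c()
    for (g in grids) {
      f <- g$field
      on_jk <- all(abs(f[-unique(c(j, k))]) < 1e-15) || length(unique(c(j, k))) == 3
      m <- max(abs(f[c(j, k)]))
      if (m > 0 && on_jk) mags <- c(mags, m)
    }
    if (!length(mags)) stop("rho2: no field-displaced grids for axes (",
                            j, ",", k, ")", call. = FALSE)
    h <- min(mags)
  }
  need <- function(f) {
    g <- .find_grid(grids, f)
    if (is.null(g))
      stop("rho2: missing grid at F = (", paste(sprintf("%g", f), collapse = ", "),
           ")", call. = FALSE)
    g
  }
  if (j == k) {
    gp <- need(uv(j, 1, h)); gm <- need(uv(j, -1, h)); gz <- need(numeric(3))
    vals <- (gp$values - 2 * gz$values + gm$values) / h^2
  } else {
    fjk <- function(s1, s2) { v <- numeric(3); v[j] <- s1 * h; v[k] <- s2 * h; v }
    vals <- (need(fjk(1, 1))$values - need(fjk(1, -1))$values -
             need(fjk(-1, 1))$values + need(fjk(-1, -1))$values) / (4 * h^2)
  }
  structure(list(origin = g0$origin, axes = g0$axes, counts = g0$counts,
                 values = vals, jk = c(j, k), h = h,
                 atoms = g0$atoms, title = sprintf("rho2_%d%d", j, k)),
            class = c("hyper_density", "grid_density"))
}

#' Beta component from a hyperpolarizability density
#'
#' Quadrature of the first spatial moment,
#' `beta_ijk = -c * integral( r_i * rho2_jk(r) dr )`, with the cell volume
#' from the axis-vector determinant. With rho2 defined as the pure second
#' field-derivative of the density, `c = 1` makes this route exactly
#' equivalent to the Taylor-coefficient beta from finite differences of
#' `mu(F) = -integral(r rho dr)`; `paper_literal = TRUE` applies the
#' printed density-analysis prefactor 1/2! instead (halving the result),
#' retained only for comparison with that convention.
#'
#' @param hd A [rho2()] result.
#' @param i Axis of the spatial moment (name or index).
#' @param paper_literal Use the 1/2! prefactor convention.
#' @param boundary_tol Warn when the largest |rho2| on the grid boundary
#'   exceeds this fraction of the global maximum (density leaking out of the
#'   box).
#' @return Scalar beta_ijk in a.u.
#' @export
beta_from_density <- function(hd, i, paper_literal = FALSE, boundary_tol = 1e-6) {
  stopifnot(inherits(hd, "hyper_density"))
  i <- .axis_index(i)
  v <- hd$values
  mx <- max(abs(v))
  if (mx > 0) {
    n <- dim(v)
    edge <- max(abs(v[c(1, n[1]), , ]), abs(v[, c(1, n[2]), ]), abs(v[, , c(1, n[3])]))
    if (edge > boundary_tol * mx)
      warning(sprintf("beta_from_density: boundary |rho2| is %.2g of max (leak)",
                      edge / mx))
  }
  c_pref <- if (paper_literal) 0.5 else 1
  -c_pref * sum(.grid_coord(hd, i) * v) * .cell_volume(hd)
}

#' Threshold a hyperdensity into isosurface-ready positive/negative grids
#'
#' @param hd A `hyper_density`.
#' @param iso Positive isovalue (a.u.); 0.25 is a typical choice for
#'   visualizing beta densities.
#' @return List with `positive` and `negative` [grid_density()] grids whose
#'   values keep rho2 where `rho2 >= iso` (resp. `<= -iso`) and are zero
#'   elsewhere, for export to external isosurface viewers.
#' @export
export_isosurface_grid <- function(hd, iso) {
  stopifnot(inherits(hd, "hyper_density"), iso > 0)
  mk <- function(mask, tag) {
    v <- hd$values
    v[!mask] <- 0
    grid_density(hd$origin, hd$axes, v, field = c(0, 0, 0),
                 atoms = hd$atoms, title = paste0(hd$title, " ", tag, " iso"))
  }
  list(positive = mk(hd$values >= iso, "+"),
       negative = mk(hd$values <= -iso, "-"))
}
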