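# Finite-field extraction of mu0, alpha, beta, gamma from dipole-vs-field
# samples, with Richardson (Romberg-style) refinement across a geometric
# ladder of field strengths.

.fkey <- function(f) {
  f[f == 0] <- 0   # normalize -0 so sign inversion round-trips
  paste(sprintf("%.12g", f), collapse = ",")
}

#' Build a finite-field stencil
#'
#' Generates the set of applied-field vectors needed for central-difference
#' extraction of response tensors up to third order (gamma) along the
#' requested axes, replicated over a geometric ladder of base field
#' strengths for Richardson refinement. The stencil always contains the
#' zero field and is closed under sign inversion.
#'
#' Per ladder rung with field strength h the stencil holds: singles
#' `+-h`, `+-2h` along each axis (the `+-2h` points only when
#' `max_order >= 3`), 4-point crosses `(+-h, +-h)` for every axis pair, and
#' the 8 corners `(+-h, +-h, +-h)` when three axes are requested and
#' `max_order >= 3`.
#'
#' @param base Base field strength in a.u. (default 0.001, balancing
#'   truncation against round-off for a.u.-scale responses).
#' @param depth Number of ladder rungs; rung s uses `base * ladder^(s-1)`.
#' @param axes Character subset of `c("x","y","z")`.
#' @param max_order Highest response order to support: 1 (alpha), 2 (beta)
#'   or 3 (gamma).
#' @param ladder Geometric factor between rungs (default 2).
#' @param cap Warn if any generated field exceeds this strength (a.u.).
#' @return Object of class `field_stencil` with the unique field matrix and
#'   the generating parameters.
#' @export
build_stencil <- function(base = 0.001, depth = 3, axes = c("x", "y", "z"),
                          max_order = 3, ladder = 2, cap = 0.05) {
  stopifnot(base > 0, depth >= 1, max_order %in% 1:3, ladder > 1)
  ax <- .axis_index(axes)
  stopifnot(length(ax) >= 1, !anyDuplicated(ax))
  rows <- list(numeric(3))
  add <- function(v) rows[[length(rows) + 1L]] <<- v
  for (s in seq_len(depth)) {
    h <- base * ladder^(s - 1)
    for (a in ax) {
      for (sg in c(-1, 1)) {
        v <- numeric(3); v[a] <- sg * h; add(v)
        if (max_order >= 3) { v[a] <- sg * 2 * h; add(v) }
      }
    }
    if (max_order >= 2 && length(ax) >= 2) {
      pr <- utils::combn(ax, 2)
      for (p in seq_len(ncol(pr))) {
        for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
          v <- numeric(3); v[pr[1, p]] <- s1 * h; v[pr[2, p]] <- s2 * h; add(v)
        }
      }
    }
    if (max_order >= 3 && length(ax) == 3) {
      for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1))
        add(h * c(s1, s2, s3))
    }
  }
  fields <- unique(do.call(rbind, rows))
  maxf <- max(abs(fields))
  if (maxf > cap)
    warning(sprintf("stencil contains fields up to %.4g a.u., above cap %.4g", maxf, cap))
  structure(list(fields = fields, base = base, depth = depth, ladder = ladder,
                 axes = ax, max_order = max_order),
            class = "field_stencil")
}

#' Dipole samples over a field stencil
#'
#' @param stencil A [build_stencil()] result.
#' @param mu Numeric matrix, one row per stencil field, columns
#'   `(mu_x, mu_y, mu_z)` in a.u.
#' @param provenance `"synthetic"` or `"external"`.
#' @return Object of class `dipole_samples`.
#' @export
dipole_samples <- function(stencil, mu, provenance = c("synthetic", "external")) {
  stopifnot(inherits(stencil, "field_stencil"))
  provenance <- match.arg(provenance)
  mu <- as.matrix(mu)
  if (nrow(mu) != nrow(stencil$fields) || ncol(mu) != 3)
    stop("mu must be a ", nrow(stencil$fields), " x 3 matrix matching the stencil",
         call. = FALSE)
  structure(list(stencil = stencil, fields = stencil$fields, mu = mu,
                 provenance = provenance),
            class = "dipole_samples")
}

#' Evaluate a dipole surface over a stencil
#'
#' @param surface Function taking a field 3-vector (a.u.) and returning the
#'   dipole 3-vector (a.u.), e.g. from [make_dipole_surface()].
#' @param stencil A `field_stencil`.
#' @param provenance Provenance tag for the resulting samples.
#' @return A [dipole_samples()] object.
#' @export
sample_dipole_surface <- function(surface, stencil, provenance = "synthetic") {
  mu <- t(apply(stencil$fields, 1, surface))
  dipole_samples(stencil, mu, provenance = provenance)
}

.sample_lookup <- function(samples) {
  keys <- apply(samples$fields, 1, .fkey)
  mu <- samples$mu
  function(f) {
    i <- match(.fkey(f), keys)
    if (is.na(i))
      stop("missing stencil point: F = (", paste(sprintf("%g", f), collapse = ", "),
           ") a.u.", call. = FALSE)
    mu[i, ]
  }
}

# single-scale central-difference estimates at field strength h
.ff_estimate <- function(get, h, ax, max_order) {
  ev <- function(...) { v <- numeric(3); d <- list(...)
    for (q in d) v[q[1]] <- v[q[1]] + q[2]; get(v) }
  mu0 <- get(numeric(3))
  alpha <- matrix(0, 3, 3); beta <- array(0, c(3, 3, 3)); gam <- array(0, rep(3, 4))
  for (j in ax) {
    fp <- ev(c(j, h)); fm <- ev(c(j, -h))
    alpha[, j] <- (fp - fm) / (2 * h)
    if (max_order >= 2) beta[, j, j] <- (fp - 2 * mu0 + fm) / h^2
    if (max_order >= 3) {
      fp2 <- ev(c(j, 2 * h)); fm2 <- ev(c(j, -2 * h))
      gam[, j, j, j] <- (fp2 - 2 * fp + 2 * fm - fm2) / (2 * h^3)
    }
  }
  if (max_order >= 2 && length(ax) >= 2) {
    pr <- utils::combn(ax, 2)
    for (p in seq_len(ncol(pr))) {
      j <- pr[1, p]; k <- pr[2, p]
      fpp <- ev(c(j, h), c(k, h));  fpm <- ev(c(j, h), c(k, -h))
      fmp <- ev(c(j, -h), c(k, h)); fmm <- ev(c(j, -h), c(k, -h))
      mixed <- (fpp - fpm - fmp + fmm) / (4 * h^2)
      beta[, j, k] <- mixed; beta[, k, j] <- mixed
      if (max_order >= 3) {
        # d^3 mu / dF_j^2 dF_k and dF_k^2 dF_j from the same cross points
        fk_p <- ev(c(k, h)); fk_m <- ev(c(k, -h))
        fj_p <- ev(c(j, h)); fj_m <- ev(c(j, -h))
        gjjk <- (fpp - 2 * fk_p + fmp - fpm + 2 * fk_m - fmm) / (2 * h^3)
        gkkj <- (fpp - 2 * fj_p + fpm - fmp + 2 * fj_m - fmm) / (2 * h^3)
        for (perm in list(c(j, j, k), c(j, k, j), c(k, j, j)))
          gam[, perm[1], perm[2], perm[3]] <- gjjk
        for (perm in list(c(k, k, j), c(k, j, k), c(j, k, k)))
          gam[, perm[1], perm[2], perm[3]] <- gkkj
      }
    }
  }
  if (max_order >= 3 && length(ax) == 3) {
    crn <- function(s1, s2, s3) ev(c(ax[1], s1 * h), c(ax[2], s2 * h), c(ax[3], s3 * h))
    gxyz <- (crn(1, 1, 1) - crn(1, 1, -1) - crn(1, -1, 1) + crn(1, -1, -1) -
             crn(-1, 1, 1) + crn(-1, 1, -1) + crn(-1, -1, 1) - crn(-1, -1, -1)) / (8 * h^3)
    for (perm in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
      gam[, ax[perm[1]], ax[perm[2]], ax[perm[3]]] <- gxyz
  }
  list(mu0 = mu0, alpha = alpha, beta = beta, gamma = gam)
}

#' Richardson/Romberg refinement of derivative estimates
#'
#' Given derivative estimates at a geometric ladder of field scales with
#' even-power (`h^2, h^4, ...`) error series, builds the triangular
#' Richardson table and returns the highest-order extrapolant. The reported
#' error estimate is the absolute difference of the last two diagonal
#' entries.
#'
#' @param estimates Two-column matrix or data.frame `(scale, value)` with
#'   at least two rows at geometrically related scales.
#' @return List with `value`, the triangular `table` (rows = scales,
#'   columns = extrapolation order), and `error` estimate.
#' @export
romberg_refine <- function(estimates) {
  est <- as.matrix(estimates)
  if (nrow(est) < 2) stop("romberg_refine: need at least 2 estimates", call. = FALSE)
  o <- order(est[, 1], decreasing = TRUE)   # largest h first
  h <- est[o, 1]; v <- est[o, 2]
  r <- h[-length(h)] / h[-1]
  if (any(abs(r / r[1] - 1) > 1e-8))
    stop("romberg_refine: scales are not a geometric ladder", call. = FALSE)
  r <- r[1]
  n <- length(v)
  tab <- matrix(NA_real_, n, n)
  tab[, 1] <- v
  for (j in 2:n) {
    f <- r^(2 * (j - 1))
    for (i in j:n)
      tab[i, j] <- (f * tab[i, j - 1] - tab[i - 1, j - 1]) / (f - 1)
  }
  err <- if (n >= 2) abs(tab[n, n] - tab[n - 1, n - 1]) else NA_real_
  list(value = tab[n, n], table = tab, error = err)
}

#' Extract response tensors from dipole-field samples
#'
#' Recovers the Taylor coefficients of the induced-dipole expansion
#' `mu_i(F) = mu_i(0) + alpha_ij F_j + (1/2!) beta_ijk F_j F_k +
#' (1/3!) gamma_ijkl F_j F_k F_l` by central differences at each ladder
#' rung of the sample stencil, followed by component-wise Richardson
#' extrapolation across rungs (when `refine = TRUE` and the stencil has
#' depth >= 2). The raw beta is jk-symmetric by construction.
#'
#' @param samples A [dipole_samples()] object.
#' @param max_order Highest order to extract (capped by the stencil's).
#' @param refine Apply Richardson refinement across ladder rungs.
#' @return List with elements `mu0` ([dipole()]), `alpha`
#'   ([alpha_tensor()]), `beta` (`beta_tensor`, jk symmetry), `gamma`
#'   ([gamma_tensor()]).
#' @export
extract_responses <- function(samples, max_order = NULL, refine = TRUE) {
  stopifnot(inherits(samples, "dipole_samples"))
  st <- samples$stencil
  if (is.null(max_order)) max_order <- st$max_order
  if (max_order > st$max_order)
    stop("stencil supports max_order ", st$max_order, call. = FALSE)
  get <- .sample_lookup(samples)
  hs <- st$base * st$ladder^(seq_len(st$depth) - 1)
  ests <- lapply(hs, function(h) .ff_estimate(get, h, st$axes, max_order))
  pick <- function(name) lapply(ests, `[[`, name)
  comb <- function(arrs, dims) {
    if (length(arrs) == 1 || !refine) return(arrs[[length(arrs)]])
    flat <- vapply(arrs, as.numeric, numeric(prod(dims)))
    out <- vapply(seq_len(nrow(flat)), function(i)
      romberg_refine(cbind(hs, flat[i, ]))$value, numeric(1))
    array(out, dims)
  }
  mu0 <- ests[[1]]$mu0   # exact: the zero-field sample itself
  alpha <- comb(pick("alpha"), c(3, 3))
  beta <- comb(pick("beta"), c(3, 3, 3))
  gam <- comb(pick("gamma"), rep(3, 4))
  list(mu0 = dipole(mu0),
       alpha = alpha_tensor(alpha, tol = 1e-6),
       beta = beta_tensor(beta, symmetry = "jk"),
       gamma = gamma_tensor(gam))
}
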