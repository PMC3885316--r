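# Independent brute-force oracles. These deliberately re-derive quantities
# from their definitions with plain loops, never calling the package code
# paths they check.

# beta_i = (1/3) sum_j (b[i,j,j] + b[j,i,j] + b[j,j,i]) on a raw array
brute_beta_components <- function(arr) {
  out <- numeric(3)
  for (i in 1:3) {
    acc <- 0
    for (j in 1:3) acc <- acc + arr[i, j, j] + arr[j, i, j] + arr[j, j, i]
    out[i] <- acc / 3
  }
  out
}

# full symmetrization of a rank-3 array by explicit permutation loop
brute_symmetrize3 <- function(arr) {
  out <- array(0, c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    p <- c(arr[i, j, k], arr[i, k, j], arr[j, i, k],
           arr[j, k, i], arr[k, i, j], arr[k, j, i])
    out[i, j, k] <- mean(p)
  }
  out
}

# double-harmonic square bracket by quadruple loop, wavenumbers in cm-1
brute_bracket <- function(modes, hartree_cm1 = 219474.6313632) {
  out <- array(0, c(3, 3, 3))
  for (m in modes) {
    w2 <- (m$wavenumber / hartree_cm1)^2
    for (i in 1:3) for (j in 1:3) for (k in 1:3)
      out[i, j, k] <- out[i, j, k] +
        (m$dmu[i] * m$dalpha[j, k] + m$dmu[j] * m$dalpha[i, k] +
         m$dmu[k] * m$dalpha[i, j]) / w2
  }
  out
}

# Raman anisotropy via the trace identity (3 Tr A^2 - (Tr A)^2) / 2,
# an algebraically independent form of the pairwise-difference definition
brute_raman_invariants <- function(A) {
  iso <- sum(diag(A)) / 3
  aniso2 <- (3 * sum(A * A) - sum(diag(A))^2) / 2
  c(iso = iso, aniso2 = aniso2)
}

# uniform-ish random rotation matrix via QR with positive diagonal
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# term-by-term polynomial dipole surface contraction (oracle for
# make_dipole_surface): explicit sums, no matrix products
brute_dipole_surface <- function(mu0, alpha, beta, gamma, F) {
  out <- numeric(3)
  for (i in 1:3) {
    v <- mu0[i]
    for (j in 1:3) v <- v + alpha[i, j] * F[j]
    for (j in 1:3) for (k in 1:3) v <- v + beta[i, j, k] * F[j] * F[k] / 2
    for (j in 1:3) for (k in 1:3) for (l in 1:3)
      v <- v + gamma[i, j, k, l] * F[j] * F[k] * F[l] / 6
    out[i] <- v
  }
  out
}

# analytic rho2_jk(r) at F=0 for a Gaussian-blob model, evaluated on the
# cubic grid used by make_density_grids (n points, half-width `extent`):
# chain rule through the field-shifted centre, closed form.
analytic_blob_rho2 <- function(m, j, k, n, extent) {
  blobs <- m$blobs
  x <- seq(-extent, extent, length.out = n)
  out <- array(0, c(n, n, n))
  X <- array(rep(x, times = n * n), c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  R <- list(X, Y, Z)
  for (q in seq_along(blobs$charges)) {
    c0 <- blobs$centers[q, ]; s2 <- blobs$sigmas[q]^2
    a <- matrix(blobs$a[[q]], 3, 3); b <- blobs$b[[q]]
    N <- blobs$charges[q] * (2 * pi * s2)^(-1.5) *
      exp(-((X - c0[1])^2 + (Y - c0[2])^2 + (Z - c0[3])^2) / (2 * s2))
    for (p in 1:3) for (r in 1:3) {
      dp <- (R[[p]] - c0[p]) / s2
      dr <- (R[[r]] - c0[r]) / s2
      H <- N * (dp * dr - (p == r) / s2)
      out <- out + H * a[p, j] * a[r, k]
    }
    for (p in 1:3) out <- out + N * (R[[p]] - c0[p]) / s2 * b[p, j, k]
  }
  out
}
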