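# Hyperpolarizability-density analysis on synthetic Gaussian-blob grids.
# Grids here are kept small (n <= 48) for speed; the 96^3 route-equivalence
# run lives in test-acceptance.R.

.xx_stencil <- function(h = 0.002) build_stencil(h, 1, axes = "x", max_order = 2)

test_that("field-independent density gives rho2 = 0 and symmetric grids", {
  bm <- gaussian_blob_model(centers = rbind(c(0.5, 0, 0), c(-0.7, 0.2, 0)),
                            charges = c(2, 3))   # a = b = 0
  grids <- make_density_grids(bm, .xx_stencil(), n = 24, extent = 7)
  # grids at F and -F identical when nothing couples to the field
  gp <- hyperpol:::.find_grid(grids, c(0.002, 0, 0))
  gm <- hyperpol:::.find_grid(grids, c(-0.002, 0, 0))
  expect_identical(gp$values, gm$values)
  hd <- rho2(grids, "x", "x")
  expect_lt(max(abs(hd$values)), 1e-12)
  expect_equal(beta_from_density(hd, "x"), 0, tolerance = 1e-12)
})

test_that("rho2 matches the analytic second field-derivative to O(h^2)", {
  bm <- random_blob_model(9, nblob = 2)
  n <- 32; extent <- 8
  grids <- make_density_grids(bm, build_stencil(0.002, 2, axes = "x", max_order = 2),
                              n = n, extent = extent)
  ana <- analytic_blob_rho2(bm, 1, 1, n, extent)
  scale <- max(abs(ana))
  expect_gt(scale, 0)
  err_h <- max(abs(rho2(grids, "x", "x", h = 0.002)$values - ana)) / scale
  err_2h <- max(abs(rho2(grids, "x", "x", h = 0.004)$values - ana)) / scale
  expect_lt(err_h, 1e-4)
  expect_gt(err_2h / err_h, 3)   # second-order convergence in the field step
  # charge conservation: the rho2 integral vanishes
  hd <- rho2(grids, "x", "x")
  expect_lt(abs(grid_integral(hd)), 1e-6 * sum(bm$blobs$charges))
})

test_that("pure linear response (b = 0) gives nonzero rho2 but zero beta", {
  a <- list(matrix(c(0.6, 0, 0, 0, 0.2, 0, 0, 0, 0.1), 3, 3))
  bm <- gaussian_blob_model(centers = rbind(c(0.3, -0.2, 0.4)), charges = 2.5,
                            a = a)
  grids <- make_density_grids(bm, .xx_stencil(), n = 32, extent = 8)
  hd <- rho2(grids, "x", "x")
  expect_gt(max(abs(hd$values)), 1e-6)
  expect_equal(beta_from_density(hd, "x"), 0, tolerance = 1e-8)
})

test_that("single-blob quadratic shift recovers the prescribed beta_xxx", {
  beta_star <- 79.3
  q <- 2
  b <- array(0, c(3, 3, 3)); b[1, 1, 1] <- -beta_star / q   # beta = -q b
  bm <- gaussian_blob_model(centers = rbind(c(0, 0, 0)), charges = q,
                            b = list(b))
  expect_equal(bm$beta[1, 1, 1], beta_star)
  grids <- make_density_grids(bm, .xx_stencil(), n = 48, extent = 8)
  bx <- beta_from_density(rho2(grids, "x", "x"), "x")
  expect_equal(bx, beta_star, tolerance = 1e-6)
})

test_that("route equivalence: density integral vs dipole-route finite differences", {
  for (seed in c(1, 12)) {
    bm <- random_blob_model(seed)
    st <- .xx_stencil()
    grids <- make_density_grids(bm, st, n = 48, extent = 9)
    b_density <- beta_from_density(rho2(grids, "x", "x"), "x")
    # dipole route on the SAME grids: mu_x(F) = -integral(x rho) per grid
    mu_of <- function(f) {
      g <- hyperpol:::.find_grid(grids, f)
      -sum(hyperpol:::.grid_coord(g, 1) * g$values) * abs(det(g$axes))
    }
    h <- 0.002
    b_dipole <- (mu_of(c(h, 0, 0)) - 2 * mu_of(c(0, 0, 0)) + mu_of(c(-h, 0, 0))) / h^2
    expect_equal(b_density, b_dipole, tolerance = 1e-10)
    # and both agree with the closed-form prescription
    expect_equal(b_density, bm$beta[1, 1, 1], tolerance = 1e-4)
  }
})

test_that("halving the grid spacing shrinks the quadrature error by >= 4x", {
  bm <- random_blob_model(6, nblob = 1)
  st <- .xx_stencil()
  err_at <- function(n) {
    grids <- make_density_grids(bm, st, n = n, extent = 9)
    abs(beta_from_density(rho2(grids, "x", "x"), "x") - bm$beta[1, 1, 1])
  }
  e_coarse <- err_at(9)    # spacing 2.25 bohr: visible quadrature error
  e_fine <- err_at(17)     # spacing halved
  expect_gt(e_coarse, 1e-10)
  expect_gt(e_coarse / e_fine, 4)
})

test_that("translation covariance and the paper-literal prefactor", {
  bm <- random_blob_model(8)
  grids <- make_density_grids(bm, .xx_stencil(), n = 32, extent = 9)
  hd <- rho2(grids, "x", "x")
  b0 <- beta_from_density(hd, "x")
  hd_shift <- hd; hd_shift$origin <- hd$origin + c(3, -2, 5)
  expect_equal(beta_from_density(hd_shift, "x"), b0, tolerance = 1e-6)
  expect_equal(beta_from_density(hd, "x", paper_literal = TRUE), b0 / 2)
})

test_that("moment sign follows the positive-to-negative orientation rule", {
  # positive rho2 lobe at lower x, negative lobe at higher x: the
  # positive->negative direction points along +x, so beta_xxx > 0
  n <- 21; x <- seq(-5, 5, length.out = n)
  lobe <- function(c0) exp(-outer(outer((x - c0)^2, x^2, `+`), x^2, `+`) / 2)
  vals <- lobe(-1.5) - lobe(1.5)
  hd <- structure(list(origin = rep(-5, 3), axes = diag(10 / (n - 1), 3),
                       counts = rep(n, 3), values = vals, jk = c(1, 1),
                       atoms = NULL, title = "toy"),
                  class = c("hyper_density", "grid_density"))
  expect_gt(beta_from_density(hd, "x", boundary_tol = 0.1), 0)
  expect_equal(beta_from_density(hd, "y", boundary_tol = 0.1), 0, tolerance = 1e-10)
})

test_that("boundary leak triggers a warning", {
  n <- 11
  vals <- array(1, c(n, n, n))   # flat density touching every face
  hd <- structure(list(origin = rep(-5, 3), axes = diag(1, 3),
                       counts = rep(n, 3), values = vals, jk = c(1, 1),
                       atoms = NULL, title = "leaky"),
                  class = c("hyper_density", "grid_density"))
  expect_warning(beta_from_density(hd, "x"), "leak")
})

test_that("rho2 input validation: geometry and stencil members", {
  bm <- random_blob_model(3)
  st <- .xx_stencil()
  grids <- make_density_grids(bm, st, n = 16, extent = 9)
  bad <- grids
  bad[[2]]$origin <- bad[[2]]$origin + 1
  expect_error(rho2(bad, "x", "x"), "mismatched geometry")
  expect_error(rho2(grids[1:2], "y", "y"), "missing grid|no field-displaced")
})

test_that("isosurface export: thresholds, disjointness, monotone counts", {
  bm <- random_blob_model(5)
  grids <- make_density_grids(bm, .xx_stencil(), n = 24, extent = 9)
  hd <- rho2(grids, "x", "x")
  mx <- max(abs(hd$values))
  empty <- export_isosurface_grid(hd, 2 * mx)
  expect_equal(sum(empty$positive$values != 0), 0)
  expect_equal(sum(empty$negative$values != 0), 0)
  iso <- mx / 4
  masks <- export_isosurface_grid(hd, iso)
  pos <- masks$positive$values != 0; neg <- masks$negative$values != 0
  expect_gt(sum(pos), 0); expect_gt(sum(neg), 0)
  expect_equal(sum(pos & neg), 0)
  counts <- vapply(mx * c(0.1, 0.3, 0.5, 0.7, 0.9), function(v) {
    mm <- export_isosurface_grid(hd, v)
    sum(mm$positive$values != 0) + sum(mm$negative$values != 0)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
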