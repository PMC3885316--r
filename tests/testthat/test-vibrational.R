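# Double-harmonic vibrational beta, per-mode contributions, IR/Raman
# intensities.

hartree_cm1 <- 219474.6313632

test_that("single-mode bracket has the closed one-term form", {
  d <- 0.04; p <- 0.6; wn <- 1800
  m <- normal_mode(1, wn, c(d, 0, 0), diag(c(p, 0, 0)))
  br <- mu_alpha_bracket(list(m))
  w2 <- (wn / hartree_cm1)^2
  expect_equal(br[1, 1, 1], 3 * d * p / w2, tolerance = 1e-12)
  br[1, 1, 1] <- 0
  expect_lt(max(abs(br)), 1e-12)   # no other component survives this pattern
})

test_that("bracket is additive over modes and matches the brute-force loop", {
  ms <- make_mode_set(30, seed = 14)
  modes <- ms$modes
  br <- mu_alpha_bracket(modes)
  expect_equal(br, brute_bracket(modes), tolerance = 1e-12)
  # recorded generator oracle agrees too
  expect_equal(br, ms$bracket, tolerance = 1e-12)
  # additivity: split the set in two
  br2 <- mu_alpha_bracket(modes[1:10]) + mu_alpha_bracket(modes[11:30])
  expect_equal(br, br2, tolerance = 1e-12)
})

test_that("scaling every wavenumber by s divides the bracket by s^2", {
  ms <- make_mode_set(8, seed = 3)
  s <- 1.7
  scaled <- lapply(ms$modes, function(m)
    normal_mode(m$index, m$wavenumber * s, m$dmu, m$dalpha))
  expect_equal(mu_alpha_bracket(scaled), ms$bracket / s^2, tolerance = 1e-12)
})

test_that("infinite-frequency process limits: SHG zero, EOPE one third", {
  ms <- make_mode_set(6, seed = 8)
  br <- mu_alpha_bracket(ms$modes)
  expect_equal(max(abs(beta_v_process(br, "SHG")$b)), 0)
  expect_equal(beta_v_process(br, "EOPE")$b, beta_tensor(br / 3, "kleinman")$b,
               tolerance = 1e-12)
  expect_equal(beta_vec(beta_v_process(br, "EOPE")), beta_vec(beta_v_process(br, "static")) / 3,
               tolerance = 1e-12)
  expect_error(beta_v_process(br, "THG"))
})

test_that("per-mode contributions: recomputation, totals, cancellation", {
  ms <- make_mode_set(10, seed = 5)
  per <- per_mode_beta_vec(ms$modes, "EOPE")
  expect_equal(nrow(per), 10)
  for (r in seq_len(10)) {
    single <- beta_vec(beta_v_process(mu_alpha_bracket(ms$modes[r]), "EOPE"))
    expect_equal(per$beta_vec[r], single, tolerance = 1e-12)
  }
  # one-mode system: per-mode value equals the total
  one <- per_mode_beta_vec(ms$modes[1], "EOPE")
  expect_equal(one$beta_vec,
               beta_vec(beta_v_process(mu_alpha_bracket(ms$modes[1]), "EOPE")))
  # opposing dipole derivatives with identical dalpha cancel in the total
  da <- diag(c(0.5, 0.2, 0.1))
  m1 <- normal_mode(1, 1000, c(0.05, 0, 0), da)
  m2 <- normal_mode(2, 1000, c(-0.05, 0, 0), da)
  tot <- beta_vec(beta_v_process(mu_alpha_bracket(list(m1, m2)), "EOPE"))
  per2 <- per_mode_beta_vec(list(m1, m2), "EOPE")
  expect_lt(tot, sum(per2$beta_vec))
  expect_equal(tot, 0, tolerance = 1e-12)
})

test_that("mode validation: imaginary modes rejected, floor excludes rotations", {
  expect_error(normal_mode(3, 500, c(1, 0, 0), matrix(c(0, 1, 0, 2, 0, 0, 0, 0, 0), 3, 3)),
               "symmetric")
  m_bad <- normal_mode(7, 100, c(0.1, 0, 0), diag(3))
  m_bad$wavenumber <- -250   # imaginary mode smuggled in
  expect_error(mu_alpha_bracket(list(m_bad)), "mode 7")
  # wavenumber floor drops pseudo-rotational junk
  low <- normal_mode(1, 10, c(5, 5, 5), diag(3) * 5)
  real <- normal_mode(2, 1500, c(0.05, 0, 0), diag(3) * 0.3)
  expect_equal(mu_alpha_bracket(list(low, real)),
               mu_alpha_bracket(list(real)), tolerance = 1e-12)
})

test_that("IR intensity: proportionality and constants from first principles", {
  m0 <- normal_mode(1, 1500, c(0, 0, 0), diag(3) * 0.1)
  expect_equal(ir_intensity(m0), 0)
  m1 <- normal_mode(1, 1500, c(0.02, -0.01, 0.03), diag(3) * 0.1)
  m2 <- normal_mode(1, 1500, 2 * m1$dmu, m1$dalpha)
  expect_equal(ir_intensity(m2), 4 * ir_intensity(m1), tolerance = 1e-12)
  # recompute the double-harmonic constant chain independently:
  NA_ <- 6.02214076e23; eps0 <- 8.8541878128e-12; c0 <- 2.99792458e8
  debye <- 1e-21 / c0; ang <- 1e-10; amu <- 1.66053906660e-27
  e <- 1.602176634e-19
  K_DA <- NA_ / (12 * eps0 * c0^2) * (debye / (ang * sqrt(amu)))^2 / 1000
  expect_equal(K_DA, 42.2561, tolerance = 1e-5)
  K_e <- K_DA * (e * ang / debye)^2
  expect_equal(K_e, 974.8802, tolerance = 1e-5)
  uc <- unit_constants()
  expect_equal(uc$K_ir_DAamu, K_DA, tolerance = 1e-12)
  expect_equal(uc$K_ir_eamu, K_e, tolerance = 1e-12)
  # and the a.u.-chain constant actually used:
  me <- 9.1093837015e-31; a0 <- 0.529177210903e-10
  K_au <- K_DA * ((e * a0 / debye) / ((a0 / ang) * sqrt(me / amu)))^2
  expect_equal(uc$K_ir_au, K_au, tolerance = 1e-12)
})

test_that("Raman activity: closed forms and brute-force invariants", {
  m0 <- normal_mode(1, 1500, c(0.1, 0, 0), matrix(0, 3, 3))
  expect_equal(raman_activity(m0), 0)
  uc <- unit_constants()
  p <- 0.4
  miso <- normal_mode(1, 1500, c(0, 0, 0), diag(3) * p)
  expect_equal(raman_activity(miso), 45 * (p * uc$dalpha_au_to_A2amu)^2,
               tolerance = 1e-12)
  set.seed(40)
  for (rep in 1:5) {
    S <- matrix(rnorm(9), 3, 3); da <- (S + t(S)) / 2
    m <- normal_mode(1, 1200, c(0, 0, 0), da)
    inv <- brute_raman_invariants(da * uc$dalpha_au_to_A2amu)
    expect_equal(raman_activity(m), 45 * inv[["iso"]]^2 + 7 * inv[["aniso2"]],
                 tolerance = 1e-12)
  }
})

test_that("mid-IR modes with strong IR*Raman dominate; X-H stretches are marginal", {
  modes <- table2_like_modes()
  per <- per_mode_beta_vec(modes, "EOPE")
  # the C=O stretch + N-H bend analogue (mode 25) is the top contributor
  expect_equal(per$index[which.max(per$beta_vec)], 25)
  # every >3000 cm-1 stretch contributes less than any of the strong
  # mid-IR modes despite sizeable intensities (the omega^2 denominator)
  hi <- per$beta_vec[per$wavenumber > 3000]
  mid <- per$beta_vec[per$index %in% c(23, 24, 25, 26)]
  expect_true(all(outer(hi, mid, `<`)))
  total <- beta_vec(beta_v_process(mu_alpha_bracket(modes), "EOPE"))
  expect_true(all(hi < 0.15 * total))
})
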