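# Shared deterministic fixtures built in code.

# A gas-phase-shaped synthetic mode set: wavenumbers / IR intensities /
# Raman activities patterned on the uracil mid-IR (strong C=O stretch +
# N-H bend pair near 1800 cm-1, weaker ring modes, plus N-H/C-H stretches
# above 3000 cm-1 that real tables omit). Derivatives are reverse-sized so
# each mode reproduces the target I_IR and A_Raman exactly (dmu along x,
# isotropic dalpha); per-mode beta values are NOT fitted to any published
# number - only the qualitative ranking is meaningful.
table2_like_modes <- function() {
  uc <- hyperpol::unit_constants()
  spec <- data.frame(
    index = c(4, 5, 11, 23, 24, 25, 26, 29, 30),
    wavenumber = c(411, 524, 783, 1523, 1711, 1802, 1828, 3210, 3580),
    I_IR = c(20, 22, 4, 127, 56, 902, 607, 100, 90),
    A_Raman = c(1, 2, 22, 11, 30, 58, 29, 70, 100)
  )
  lapply(seq_len(nrow(spec)), function(r) {
    d <- sqrt(spec$I_IR[r] / uc$K_ir_au)
    p <- sqrt(spec$A_Raman[r] / 45) / uc$dalpha_au_to_A2amu
    hyperpol::normal_mode(spec$index[r], spec$wavenumber[r],
                          c(d, 0, 0), diag(p, 3),
                          label = if (spec$wavenumber[r] > 3000) "stretch X-H"
                                  else "mid-IR mode")
  })
}
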