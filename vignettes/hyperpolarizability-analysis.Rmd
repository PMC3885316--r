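---
title: "Electronic and vibrational first-order hyperpolarizabilities: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electronic and vibrational first-order hyperpolarizabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperpol)
```

## The problem

Second-order nonlinear optical (NLO) behaviour of a molecule — frequency
doubling (SHG), the electro-optic Pockels effect (EOPE) — is governed at the
microscopic level by the first-order hyperpolarizability tensor
$\beta_{ijk}$, the quadratic response of the molecular dipole to an applied
electric field:

$$\mu_i(\mathbf F) = \mu_i(0) + \alpha_{ij}F_j + \tfrac{1}{2!}\beta_{ijk}F_jF_k
  + \tfrac{1}{3!}\gamma_{ijkl}F_jF_kF_l + \cdots$$

Nucleic-acid bases such as uracil are candidate bio-sourced NLO materials,
and solvation changes their $\beta$ dramatically: the solvent reaction
field reshapes both the electronic response and, via shifted vibrational
frequencies and intensities, the pure vibrational response. This package
provides the desk-scale analysis layer around that physics: it consumes
response data (from quantum-chemistry engines or from its own synthetic
generator), extracts and reduces tensors, and reproduces the standard
derived quantities — invariants, vibrational contributions, density maps,
spectra, dispersion and solvent ratios.

**Conventions fixed once and used everywhere:**

* $\beta_{ijk} \equiv \partial^2\mu_i/\partial F_j\partial F_k$ at
  $\mathbf F = 0$ (Taylor convention; the $1/2!$ of the expansion cancels
  the derivative factor). Perturbation-series data must be rescaled before
  import.
* All internal numbers are atomic units; conversion happens only at I/O
  edges through `unit_constants()` (CODATA 2018). The package hard-codes
  no derived conversion factor: the $\beta$ a.u.→SI factor
  $e^3a_0^3E_h^{-2} = 3.206361\times 10^{-53}\,\mathrm{C^3m^3J^{-2}}$, the
  dipole factor 2.541746473 D/a.u. and 219474.63 cm$^{-1}$/hartree are all
  recomputed from the fundamental constants at run time.

## Tensor reduction

`beta_tensor()` enforces a declared index symmetry on construction:
*Kleinman* (all permutations, the appropriate symmetry for static response
far from resonance, and the default because published static tables list
only $\beta_{ijj}$-type components) or *jk* (last two indices, what a
finite-field second derivative delivers). The reported invariant is

$$\beta_{vec} = \sqrt{\beta_x^2+\beta_y^2+\beta_z^2},\qquad
  \beta_i = \tfrac13\sum_{j}(\beta_{ijj}+\beta_{jij}+\beta_{jji}),$$

which is rotation invariant (tested with random rotations to $10^{-10}$)
and insensitive to full symmetrization of the raw tensor — an exact
algebraic identity the test suite checks by brute force. No
hyper-Rayleigh invariant or depolarization ratios are computed. For a
planar ($C_s$) molecule in the $xz$ plane, $\beta_y$ vanishes by symmetry;
the package computes all three components and lets tests assert
$\beta_y \approx 0$ rather than hard-coding it.

```{r}
b_gas <- beta_from_components(c(zxx = -106.5, zyy = -36.5, zzz = 78.2,
                                xxx = 79.3, xyy = 19.5, xzz = 5.7))
beta_components(b_gas)
beta_vec(b_gas)
```

## Finite-field extraction

`build_stencil()` / `extract_responses()` implement numerical
differentiation of the dipole expansion: central differences for
$\alpha$ (2-point), $\beta$ (3-point diagonal, 4-point cross), $\gamma$
(5-point diagonal, cross combinations, 8-corner for three distinct axes),
repeated on a geometric ladder of base fields and combined by Richardson
extrapolation (`romberg_refine()`), which assumes an even-power error
series — exact for the symmetric stencils used.

Numerical choices: default base field $10^{-3}$ a.u., ladder factor 2,
depth 3. The base balances truncation ($\propto h^2\gamma$) against
round-off ($\propto \varepsilon/h^2$ for $\beta$, $\varepsilon/h^3$ for
$\gamma$) for responses of the magnitude seen in small organic molecules
($\beta \sim 10$–$300$ a.u., $\gamma \sim 10^3$). A warning fires above a
0.05 a.u. field cap, where the truncated expansion itself stops being
trustworthy. Frequency-dependent $\beta(-2\omega;\omega,\omega)$ and
$\beta(-\omega;\omega,0)$ are *not* computed by finite fields — that
requires a time-dependent electronic-structure engine — and enter only as
data through the dispersion module.

## Hyperpolarizability densities

The spatial origin of $\beta$ is analysed through the density expansion
$\rho(\mathbf r,\mathbf F)$ in powers of the field. The second-derivative
density $\rho^{(2)}_{jk}(\mathbf r)$ is built pointwise from cube-format
grids at stencil fields, and its first moment gives back the tensor:

$$\beta_{ijk} = -c\int r_i\,\rho^{(2)}_{jk}(\mathbf r)\,d\mathbf r .$$

**Prefactor decision.** With $\rho^{(2)}$ defined as a pure second
derivative, $c = 1$ is the only choice consistent with the Taylor
convention above; the widely printed $-1/2!$ prefactor belongs to the
variant where $\rho^{(2)}$ is the *expansion coefficient* (which already
carries the $1/2!$). The package defaults to $c = 1$ so that the density
route and the dipole route agree identically on the same grids (they are
then the same linear functional of the data); `paper_literal = TRUE`
applies the $1/2!$ for comparison with that convention. A
positive-to-negative lobe pattern oriented along $+i$ gives a positive
$\beta$ contribution, matching the usual reading of such maps.

Quadrature is midpoint with the cell volume from the axis determinant;
the default field step for density differentiation is 0.002 a.u.
(densities are noisier than dipoles); a boundary-leak check warns when
$|\rho^{(2)}|$ on the box faces exceeds $10^{-6}$ of its maximum.
`export_isosurface_grid()` writes thresholded $\pm$iso grids for external
viewers; no rendering is attempted here.

## Vibrational response

The double-harmonic pure vibrational $\beta$ is the lowest square-bracket
term summed over the $3N-6$ genuine normal modes:

$$[\mu\alpha]^{0,0}_{ijk} = \sum_a
 \frac{(\partial\mu_i/\partial Q_a)(\partial\alpha_{jk}/\partial Q_a)
 + (\partial\mu_j/\partial Q_a)(\partial\alpha_{ik}/\partial Q_a)
 + (\partial\mu_k/\partial Q_a)(\partial\alpha_{ij}/\partial Q_a)}{\omega_a^2}$$

with $\omega_a$ converted from cm$^{-1}$ to hartree *before* squaring —
the only reading that yields $\beta$ in atomic units. In the
infinite-optical-frequency limit,
$\beta^v(-2\omega;\omega,\omega) = 0$ and
$\beta^v(-\omega;\omega,0) = \tfrac13[\mu\alpha]^{0,0}$
(`beta_v_process()`). Translations/rotations are excluded by a 50
cm$^{-1}$ wavenumber floor with explicit override; imaginary modes are a
hard error naming the mode. No anharmonic, $[\mu^3]$-curvature or
zero-point corrections are included — the model is deliberately
double-harmonic only.

Per-mode $\beta_{vec}$ values (`per_mode_beta_vec()`) are norms of
per-mode vectors; because the total is a vector composition they do not
sum to the total $\beta_{vec}$, and the package always computes totals
from the summed tensor. Whether published per-mode values are norms or
signed projections is ambiguous in practice; norms are computed here and
the assumption is recorded. The $\omega_a^{-2}$ weight explains the
characteristic ranking: intense mid-IR carbonyl-stretch/N–H-bend modes
dominate while X–H stretches above 3000 cm$^{-1}$ are marginal despite
sizeable intensities — a rank-ordering property the tests assert on a
synthetic, table-shaped mode set (per-mode magnitudes are *not* fitted to
any published value; the underlying derivatives are unpublished, so only
ratios of printed values are testable).

IR intensities use $I = K|\partial\mu/\partial Q|^2$ with
$K = N_A/(12\varepsilon_0 c^2)$, i.e. 42.2561 km/mol for derivatives in
D Å$^{-1}$ amu$^{-1/2}$, equivalently 974.8802 for $e\,$amu$^{-1/2}$, or
$1.777\times10^6$ for the package's fully atomic-unit storage convention
(per mass-weighted a.u. coordinate); all three are derived from constants
at run time and cross-checked in the tests. Raman activities are
$45\bar\alpha'^2 + 7\bar\gamma'^2$ in Å$^4$/amu.

## Spectra, dispersion, ratios

`broaden()` uses **area-normalized** Lorentzians (FWHM default 10
cm$^{-1}$), so the integral over an isolated band equals its stick
intensity; the alternative peak-normalized convention is common in plots
but loses the intensity bookkeeping, and published y-axis conventions are
often unspecified — area normalization is stated here for that reason.
Raman spectra are plotted from activities as given, with no
frequency-dependent scattering cross-section correction.

`dispersion_series` objects carry $(\hbar\omega, \beta_{vec})$ samples per
process and phase over 0–0.06563 a.u. (the upper anchor is the ruby-laser
wavelength, 694 nm). Lookup is nearest-sample with exact-match preference
and *no extrapolation*; `dispersion_percent()`, `solvent_ratio()` and
`find_crossing()` (first sign change of the difference, located by linear
interpolation) are thin, well-tested reductions on top. No
resonance-damping model is included: the relevant excitation energies lie
far above $2\hbar\omega_{max}$, so undamped dispersion is the appropriate
regime.

## The synthetic generator, and what a green test establishes

Published DFT responses are not desk-reproducible, so the test oracle is a
family of model molecules with *analytically known* responses:

* **Polynomial dipole surfaces** with prescribed
  $(\mu_0, \alpha, \beta, \gamma)$ — the finite-field module must recover
  the prescription to $10^{-8}$ relative (it does, essentially to machine
  precision, because the surface is exactly cubic).
* **Random mode sets** with recorded closed-form brackets — the
  vibrational module must agree to $10^{-12}$.
* **Gaussian-blob densities** whose centres shift with the field,
  $c(F) = c_0 + aF + \tfrac12 b(F\otimes F)$, giving
  $\beta_{ijk} = -\sum_b q_b\,b_{i,jk}$ in closed form with no electronic
  structure at all (widths default 1 bohr, charges form a mock electron
  count). Prescription, dipole route and density route must agree
  pairwise — the repository's master oracle triangle.

Scales are chosen once to mirror the molecular regime (β in the 10–300
a.u. decade, α tens of a.u., mid-IR wavenumbers 400–3700 cm$^{-1}$,
derivative scales matched to intense fundamentals:
$|\partial\mu/\partial Q| \approx 0.02$ a.u. corresponds to a
$\sim$900 km/mol band, $|\partial\alpha/\partial Q| \approx 0.2$ a.u. to
a $\sim$60 Å$^4$/amu one) and are not tuned to any test outcome; note
that random low-wavenumber modes given such derivatives contribute far
more than real low-frequency modes do, because in real molecules weak
derivatives accompany low frequencies — the generator makes no attempt to
correlate the two. What these fixtures do **not**
emulate: basis-set/functional error, PCM reaction-field physics, density
cusps and diffuse tails of real charge distributions, anharmonicity, and
mode mixing. A green suite therefore establishes that the *analysis
machinery* is correct and internally consistent — not that any particular
electronic-structure prediction is right.

The packaged JSON fixture stores published gas/water reference values
verbatim as printed, and golden tests use absolute tolerances matched to
print precision (±0.15 a.u. on table-derived sums, ±0.01 D, ±0.2
percentage points) rather than pretending more digits exist. One known
internal inconsistency of the source tables is preserved deliberately:
the printed dipole increase "1.4 D" does not match the printed totals
(6.25 − 4.57 = 1.68 D), while the printed +37% does; the fixture stores
both and the golden test targets the percentage. Dispersion curves
between the two printed anchors are synthetic fill with the documented
qualitative shape (water SHG crossing water EOPE near
$\hbar\omega \approx 0.045$ a.u.); only anchor values and the crossing
window are asserted.

## Known limitations

* Dipole-based extraction only; no energy-based (fourth-derivative)
  finite-field route.
* $\rho^{(3)}$ (γ-density) analysis is not implemented.
* Dynamic β tensors are consumed as data, never computed.
* The cube reader accepts the two common unit dialects (sign of the voxel
  count) but not checkpoint or binary formats.
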