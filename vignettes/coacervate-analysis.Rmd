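---
title: "Methods: from bench measurements to droplet interfacial tension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from bench measurements to droplet interfacial tension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coacervkit)
```

coacervkit implements the quantitative chain used to characterize
short-peptide coacervates: what charge states a peptide populates at a
given pH, how to mix it with an oppositely charged partner at a target
charge ratio, how turbid a phase-separating sample is, what the dissolved
monomer looks like in SAXS, how large the droplets are by DLS, and —
pulling size and zeta potential together — what interfacial tension the
droplets carry. This vignette describes each model, its assumptions, the
tunable parameters, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## 1. Charge speciation

### Model

Each ionizable group $i$ (N-terminus, C-terminus, ionizable side chains)
is treated as an independent protonation site with its own p$K_a$. The
protonation probability at a given pH is the Henderson–Hasselbalch form

$$p_i = \frac{1}{1 + 10^{\,\mathrm{pH} - \mathrm{p}K_{a,i}}},$$

a basic group contributes charge $+p_i$ in expectation, an acidic group
$-(1 - p_i)$. The fractional net charge is the sum; it is strictly
decreasing in pH, so the isoelectric point is its unique zero.
`speciation()` convolves the per-site two-point charge distributions into
the distribution over integer net charges. Independence makes this
convolution *exactly* equal to Boltzmann enumeration of all $2^N$
protonation microstates, which the test suite verifies to $10^{-9}$ up to
$N = 12$ sites.

### Assumptions and parameters

- **Site independence.** No site–site interaction terms and no
  environment-dependent p$K_a$ shifts. For short peptides with few charged
  groups this is the standard working assumption; strongly coupled sites
  (e.g. adjacent carboxylates) would need a microstate model with
  interaction energies, which is out of scope.
- **p$K_a$ table** (`default_pka_table()`): N-term 9.0, C-term 3.1,
  Asp 3.65, Glu 4.25, His 6.0, Cys 8.3, Tyr 10.1, Lys 10.5, Arg 12.5 (pH
  units). These are textbook intrinsic values. The table is a named,
  swappable argument everywhere (and loadable from CSV with
  `read_pka_csv()`) because any serious use should substitute p$K_a$s
  measured for the actual peptide: published isoelectric points computed
  from measured p$K_a$ sets will generally not be reproduced exactly by
  the default table.
- **Titration charge balance** (`base_to_reach_pH()`,
  `titration_curve()`): solves
  $[\mathrm{Na}^+] + [\mathrm{H}^+] + C_p Z(\mathrm{pH}) =
  [\mathrm{OH}^-] + C_p\, n_\mathrm{TFA}$
  for the added strong base. Peptides supplied as trifluoroacetate salts
  carry `tfa_per_molecule` counterions (default: one per basic group, the
  fully protonated supply form), treated as fully dissociated spectator
  anions — TFA's own p$K_a$ (~0.2) is far below any pH of interest here.
  Activity coefficients are neglected (ideal-solution balance).

### Numerics

The isoelectric point is found by bisection on pH ∈ [0, 14] to
$|Z| < 10^{-6}$ (monotonicity guarantees uniqueness); an all-basic or
all-acidic group set raises an error rather than returning a boundary
value. The forward titration solve brackets on pH ∈ [10⁻⁶, 14−10⁻⁶] with
`uniroot` at tolerance 10⁻¹⁰. Masses are reported to two decimals with
round-half-up, matching the convention of synthesis certificates; the
underlying residue tables are standard monoisotopic and average values.

## 2. Formulation arithmetic

Weight percent is defined as g per 100 mL with solution density 1 g/mL
(dilute aqueous samples), so molarity $= 10\,w/M$. For a
charge-ratio-matched mixture the partner molarity is
peptide molarity × peptide charge × ratio ÷ |partner charge|; the
resulting wt % is rounded half-up to one decimal, the precision at which
such compositions are conventionally reported. ATP defaults to its
disodium salt (551.14 g/mol) with an assumed integer charge of −2 near
neutral pH; the free-acid mass can be passed instead. The peptide's
assumed integer charge is the user's choice (typically the number of
arginines for Wₙ Rₙ-type sequences).

Turbidity is the attenuation per path length implied by the decadic
absorbance at 500 nm, $T = \ln(10)\,A/L$ (cm⁻¹) — at that wavelength the
peptides have no intrinsic absorbance, so all attenuation is droplet
scattering. `assemble_phase_map()` does no modelling: it organizes a
measured (or synthetic) turbidity grid into LLPS flags at a user-chosen
threshold, with the boundary convention that a point exactly at threshold
counts as phase separated.

## 3. Droplet electrostatics: the tension estimate

### Model

A charged droplet holds its charge on the surface. At the Rayleigh
stability limit, electrostatic repulsion balances interfacial tension and
the limit charge for a droplet of diameter $d$ is

$$q = \pi \sqrt{8 \varepsilon_0 \gamma d^3},$$

equivalently, in terms of surface charge density
$\sigma = q / \pi d^2$,

$$d = \frac{8 \varepsilon_0 \gamma}{\sigma^2}
\qquad\Longleftrightarrow\qquad
\gamma = \frac{d\,\sigma^2}{8 \varepsilon_0}.$$

These two forms are algebraically equivalent; the test suite checks their
mutual consistency to $10^{-9}$ relative across a log grid of
$d \in [10\,\mathrm{nm}, 10\,\mu\mathrm{m}]$,
$\gamma \in [10^{-5}, 10^{-1}]$ N/m.

The surface charge density comes from the measured zeta potential via the
Grahame equation. Two modes are provided:

- `linear` (default): $\sigma = \varepsilon \varepsilon_0 \kappa \psi_0$,
  valid at low potential;
- `full_1to1`: $\sigma = 2 \varepsilon \varepsilon_0 \kappa (k_B T / e)
  \sinh\!\big(e \psi_0 / 2 k_B T\big)$ for a symmetric 1:1 electrolyte.

At 1 mV the two agree to better than $10^{-4}$ relative (first-order
agreement is a tested invariant), so for coacervate droplets with
mV-scale zeta potentials the linearized form is fully adequate. The real
electrolyte in a pH-adjusted TFA-salt sample is a mixture (Na⁺, OH⁻,
TFA⁻, peptide ions); neither mode models that mixture exactly, which is
one reason the linearized form — agnostic to composition — is the
default.

### Assumptions

- Observed droplets sit **at** the Rayleigh stability limit. This is the
  interpretive step that turns a size + potential pair into a tension; if
  droplets are below the limit the estimate is an upper bound construction
  rather than an equality.
- The zeta potential is used directly as the surface potential $\psi_0$
  (no slip-plane correction), and the Debye length is an input
  (`electrolyte_env()`), not computed from the recipe — the full ionic
  composition of a titrated sample is rarely known. When an ionic
  strength is supplied instead, $\kappa^{-1} =
  \sqrt{\varepsilon \varepsilon_0 k_B T / (2 N_A e^2 \cdot 1000 I)}$,
  and a simultaneously supplied Debye length must agree to $10^{-6}$
  relative.
- Defaults: $\varepsilon = 78.4$, $T = 298$ K (water near room
  temperature); constants are CODATA 2018 values
  (`physical_constants()`).

`tension_from_measurements()` chains Grahame → tension → limit charge and
echoes all inputs in its one-row-per-droplet tibble so results are
self-describing.

## 4. Composite SAXS model

### Model

Two variants cover the two sample states:

- **coacervate**: $I(q) = I_s q^{-n} + S\,P_{gg}(q; R_g, \nu) + B$.
  The power law (Porod exponent fixed at $n = 4$ by default — scattering
  from the sharp interfaces of discrete droplets) captures the strong
  low-$q$ upturn of a phase-separated sample; the generalized Gaussian
  coil captures the dissolved monomer at high $q$.
- **monomer**: $I(q) = S\,P_{gg}(q)\,S_{peak}(q) + B$, with an empirical
  correlation peak $S_{peak}(q) = 1 + c / (1 + (|q - q_0| \xi)^m)$ for
  the intermolecular-correlation maxima concentrated monomer solutions
  show near $q \approx 0.1\,\text{Å}^{-1}$. The peak form is
  deliberately generic (amplitude $c$, position $q_0$, correlation length
  $\xi$, shape $m$, default 2): it is a descriptive interference term,
  not a liquid-state structure factor.

The generalized Gaussian coil is the Benoit excluded-volume chain,

$$P_{gg}(q) = \frac{1}{\nu U^{1/2\nu}} \gamma\!\left(\tfrac{1}{2\nu}, U\right)
 - \frac{1}{\nu U^{1/\nu}} \gamma\!\left(\tfrac{1}{\nu}, U\right),
\qquad U = \frac{q^2 R_g^2 (2\nu + 1)(2\nu + 2)}{6},$$

with $\gamma(s, x)$ the lower incomplete gamma function (evaluated via
`pgamma`). At $\nu = 1/2$ this reduces exactly to the Debye function
(tested to $10^{-6}$ relative over $qR_g \in [0.01, 10]$); the high-$q$
decay exponent is $1/\nu$, so fitted $\nu < 1/2$ indicates a compressed
conformation. Below $U = 10^{-4}$ a two-term series replaces the direct
expression to avoid 0/0 at $q \to 0$; $I(0) = S + B$ exactly.

### Fitting

`fit_saxs()` is weighted nonlinear least squares: residuals
$(I_{model} - I)/\sigma$ when the curve carries uncertainties, unweighted
otherwise, minimized by Levenberg–Marquardt with box bounds
(`minpack.lm::nls.lm`; bounds enforce $R_g > 0$, $\nu \in [0.2, 1]$,
non-negative amplitudes and background). Parameters named in `fixed` are
held at their initial values; the coacervate default fixes $n = 4$ and
the monomer default fixes the peak shape $m = 2$. Standard errors come
from the Gauss–Newton covariance scaled by the reduced chi-square
(`NA` when the hessian is singular, e.g. a parameter pinned at a bound);
non-convergence sets a flag instead of raising. The fit is covariant
under intensity rescaling — multiplying $I$ and $\sigma$ by $k$ scales the
amplitudes by $k$ and leaves $R_g$, $\nu$, $n$ unchanged — which the
suite checks to $10^{-6}$.

## 5. DLS: forward model and regularized inversion

### Forward model

For an intensity-basis distribution of hydrodynamic radii $w_i$ at
$R_{h,i}$, the field autocorrelation is
$g_1(\tau) = \sum_i w_i e^{-D_i q^2 \tau}$ with
$D_i = k_B T / 6 \pi \eta R_{h,i}$ (Stokes–Einstein) and
$q = 4\pi n \sin(\theta/2)/\lambda$; the measured quantity follows the
Siegert relation $g_2 - 1 = \beta g_1^2$. Instrument defaults describe a
He–Ne goniometer (632.8 nm, 90°, water at 298 K, η = 0.89 mPa·s), all
overridable via `dls_instrument()`.

### Inversion

`invert_g2()` recovers $w \ge 0$ on a log-spaced radius grid (default 60
points, 1 nm–10 μm) by Tikhonov-regularized non-negative least squares:

$$\min_{w \ge 0} \| K w - g_1 \|^2 + \alpha^2 \| L_2 w \|^2,$$

with $K_{ij} = e^{-D_j q^2 \tau_i}$ and $L_2$ the second-difference
(smoothness) operator, solved by `pracma::lsqnonneg` on the augmented
system. This is the same constrained-regularization idea as CONTIN;
settings of proprietary correlator software are not reproduced.

Two numerical choices matter and are worth stating explicitly:

- **Sign-preserving Siegert inversion.** $g_1$ is taken as
  $\mathrm{sign}(y)\sqrt{|y|}$, $y = (g_2-1)/\beta$. Clipping negative
  baseline noise to zero before the square root rectifies the tail into a
  systematically positive $g_1$, which the exponential kernel can only
  fit with large-radius components — in round-trip experiments this
  inflated the intensity-weighted mean diameter by roughly 20%. Keeping
  the sign lets tail noise average out.
- **Automatic regularization by a noise-floor discrepancy rule.**
  `alpha = "auto"` picks the largest α on a log grid whose residual norm
  stays within a factor 1.002 of the smallest-α residual. The more common
  L-curve corner criterion was implemented and evaluated first, but under
  non-negativity the residual branch of the L-curve is almost flat (the
  baseline-noise floor dominates it), so corner detection lands far past
  the knee and over-smooths — the same round-trip experiments showed a
  10–19% upward bias in the mean diameter. The discrepancy rule keeps the
  fit at the noise floor while taking as much smoothing as the data
  permit. A numeric `alpha` overrides it; `alpha = 0` performs the
  unregularized (ill-conditioned) inversion with a warning.

The recovered distribution is intensity-basis and normalized;
conversions to volume or number weighting are intentionally out of scope
(they require optical contrast models). The headline summary is the
intensity-weighted mean diameter $\bar d = 2 \sum_i w_i R_{h,i}$.

## 6. Synthetic data: what it emulates, and what it does not

All generators are seeded, return `(data, truth)` pairs, and restore the
global RNG state. Their defaults are the study conditions the rest of the
package is exercised against:

- `gen_saxs()`: 200 log-spaced $q$ points over 0.004–0.4 Å⁻¹ with 2%
  multiplicative Gaussian noise (relative error structure, typical of
  scaled detector data); coacervate truth $R_g = 9.23$ Å, $\nu = 0.4$,
  $n = 4$, with Porod amplitude $10^{-8}$ and background $0.01$ on a
  unit coil scale — amplitudes chosen once so the power law dominates the
  low-$q$ decade and the coil the high-$q$ decade, the regime the
  composite model is for. The declared `sigma` column equals the
  generating noise level, so weighted fits use the true weights.
- `gen_dls()`: log-normal droplet ensembles whose intensity-weighted mean
  diameter is pinned exactly to the requested value (default 1.3 μm,
  geometric SD 1.1, β = 0.9, additive noise $10^{-3}$ — the error of a
  well-averaged correlator trace) on a 240-point lag grid spanning
  $10^{-5}$–$10^3$ s.
- `gen_titration()`: forward charge-balance solve over a NaOH grid, with
  optional pH-meter noise (0.02 pH is typical).
- `gen_turbidity_grid()`: a sigmoidal turbidity surface across a linear
  phase boundary in the (concentration, pH) plane, plus additive noise.

Passing the round-trip suites on these inputs demonstrates that each
inversion/fit stage is a faithful inverse of the corresponding forward
model at realistic noise — it does **not** demonstrate robustness to the
ways real instruments deviate from the forward models: SAXS buffer
mis-subtraction, smearing, or inter-droplet structure factors; DLS number
fluctuations, dust, multiple scattering, or sedimentation of μm-scale
droplets; electrode drift in titrations. Real data should be inspected
with those failure modes in mind.

## 7. Interfaces

Every analysis stage is a plain function taking and returning tibbles (or
small S3 records with `tidy()`/`glance()`/`autoplot()` methods), so the
natural interface is the R console or a pipeline script. File formats are
the field's plain-text conventions: 2/3-column ASCII for SAXS curves and
correlograms (`#` comments; a `# beta =` annotation carries the coherence
factor), CSV for p$K_a$ tables, speciation tables, turbidity grids and
phase maps. A thin command-line wrapper (`inst/cli/coacervkit`, exposed
programmatically as `run_cli()`) provides the subcommands `props`,
`formulate`, `tension`, `saxs-fit`, `dls-invert`, `synth` and
`phase-map`; options can come from a `key = value` config file with
explicit flags taking precedence, unknown options are rejected, and
outputs are byte-stable JSON/CSV. The config format is deliberately a
minimal `key = value` file rather than a full TOML dialect.

## 8. Known limitations

- The tension estimate inherits the at-the-Rayleigh-limit assumption and
  the dispersity of the droplet population: a single "average" diameter
  hides a distribution of tensions.
- Default p$K_a$ values are intrinsic textbook constants; published
  isoelectric points based on measured p$K_a$s will differ.
- The linearized Grahame form ignores the actual mixed electrolyte;
  the `full_1to1` option assumes a symmetric 1:1 salt.
- The DLS inversion reports intensity-weighted quantities only, on a
  fixed log grid; multi-angle global analysis and cumulant expansions are
  not implemented.
- SAXS fitting covers the two printed model variants only; no model
  selection, absolute calibration, or instrument smearing.
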