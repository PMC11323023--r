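# coacervkit

Quantitative analysis of peptide coacervation (liquid–liquid phase
separation, LLPS) experiments, for researchers characterizing short-peptide
or polyelectrolyte condensates with the standard bench toolkit: pH
titration, UV–vis turbidity, zeta potential, dynamic light scattering (DLS)
and small-angle X-ray scattering (SAXS).

The package covers five connected stages:

1. **Peptide charge speciation** — multi-site Henderson–Hasselbalch
   ionization of a sequence's termini and side chains: fractional net
   charge, integer charge-state distributions, isoelectric point, and the
   NaOH charge balance behind titration curves.
2. **Formulation stoichiometry** — wt % ↔ molarity conversions,
   peptide:partner (e.g. ATP) compositions at a target charge ratio, and
   turbidity phase maps from absorbance grids.
3. **Droplet electrostatics** — the core model: a charged coacervate
   droplet sits at its Rayleigh stability limit, so its measured size and
   zeta potential yield the interfacial tension.
4. **SAXS fitting** — a composite model, Porod power law
   \(I_s q^{-n}\) for the droplet interfaces plus a generalized Gaussian
   coil (excluded-volume chain, parameters \(R_g\) and Flory \(\nu\)) for
   the dissolved monomer, with an optional correlation-peak structure
   factor for concentrated monomer solutions.
5. **DLS inversion** — CONTIN-style regularized non-negative inversion of
   intensity autocorrelation functions to hydrodynamic-radius
   distributions via the Siegert relation and Stokes–Einstein closure.

A seeded synthetic-data module (`gen_saxs()`, `gen_dls()`,
`gen_titration()`, `gen_turbidity_grid()`) generates every input the
pipeline consumes with known ground truth, so all stages are testable
offline.

## The droplet-tension model

A droplet of diameter *d* carrying surface charge is torn apart by Coulomb
repulsion once its charge exceeds the Rayleigh limit, where electrostatic
pressure balances interfacial tension γ:

    q = π √(8 ε₀ γ d³)        (limit charge)
    d = 8 ε₀ γ / σ²           (diameter at the limit, σ = q/πd²)

The surface charge density σ follows from the measured zeta potential ψ₀
through the low-potential (linearized) Grahame equation,

    σ = ε ε₀ κ ψ₀,

with κ the inverse Debye length and ε the relative permittivity. Assuming
observed droplets sit at the stability limit, the measured (d, ψ₀) pair
gives the interfacial tension γ = d σ² / (8 ε₀) — a non-invasive tension
estimate requiring only light-scattering and electrophoretic-mobility
measurements.

## Worked example

A 1.3 μm droplet population with ψ₀ = 1.1 mV at a 2.42 nm Debye length:

```r
library(coacervkit)
env <- electrolyte_env(debye_length_nm = 2.42)  # water, 298 K, eps 78.4
tension_from_measurements(diameter_um = 1.3, zeta_mV = 1.1, env)
#> # A tibble: 1 × 9
#>   diameter_um zeta_mV debye_nm epsilon temperature_K grahame_mode sigma_mC_m2
#>         <dbl>   <dbl>    <dbl>   <dbl>         <dbl> <chr>              <dbl>
#> 1         1.3     1.1     2.42    78.4           298 linear             0.316
#> # ℹ 2 more variables: gamma_mN_m <dbl>, limit_charge_C <dbl>
```

σ ≈ 0.32 mC m⁻² and (in the hidden columns) γ ≈ 1.8 mN m⁻¹ with a limit
charge of ~1.7 fC: the droplet interface is very weakly charged, and the
inferred tension sits at the upper end of the 10⁻⁴–1 mN m⁻¹ range reported
for biomolecular condensates.

Fitting a synthetic coacervate SAXS curve (2 % noise) from deliberately
wrong starting values recovers the generating monomer size:

```r
synth <- gen_saxs(seed = 1)     # truth: rg 9.23 A, nu 0.4, Porod n = 4
fit <- fit_saxs(synth$curve, "coacervate",
                saxs_params(rg = 14, nu = 0.6, coil_scale = 1.5,
                            porod_amplitude = 1.5e-8, background = 0.015))
tidy(fit)
#> # A tibble: 6 × 4
#>   term                estimate std.error fixed
#>   <chr>                  <dbl>     <dbl> <lgl>
#> 1 porod_amplitude 0.0000000100  3.53e-11 FALSE
#> 2 porod_exponent  4            NA        TRUE
#> 3 coil_scale      1.01          1.19e- 2 FALSE
#> 4 rg              9.23          4.19e- 2 FALSE
#> 5 nu              0.422         2.46e- 2 FALSE
#> 6 background      0             1.08e- 2 FALSE
```

The radius of gyration comes back at 9.23 ± 0.04 Å. `autoplot(fit)` draws
the log–log data/model overlay; `invert_g2()` + `autoplot()` do the same
for DLS correlograms.

A shell entry point wrapping the same functions ships at
`inst/cli/coacervkit`:

```sh
Rscript inst/cli/coacervkit tension --diameter-um 1.3 --zeta-mv 1.1 --debye-nm 2.42
Rscript inst/cli/coacervkit synth saxs_coacervate --seed 7 --out out/
Rscript inst/cli/coacervkit saxs-fit out/saxs_curve.dat --variant coacervate --fix n=4
```

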