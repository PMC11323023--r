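#' Seeded synthetic-data generators
#'
#' Each generator returns a `(data, truth)` pair so that every analysis
#' stage in the package can be exercised against known ground truth without
#' instrument data. All randomness flows from the single `seed` argument;
#' the same seed reproduces the output exactly. Default scenario parameters
#' are pinned to the measured system the package models: a W2R2-like
#' monomer (radius of gyration 9.23 Angstrom) inside a coacervate with
#' Porod exponent 4, and droplet ensembles with a 1.3 um intensity-weighted
#' mean diameter.
#'
#' @name synthetic_data
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  force(code)
}

#' @rdname synthetic_data
#' @param seed Integer seed.
#' @param truth Ground-truth [saxs_params()]; defaults to the pinned
#'   coacervate scenario (rg 9.23, nu 0.4, Porod exponent 4) or, for the
#'   monomer variant, the same coil with a correlation peak near
#'   q = 0.1 1/Angstrom.
#' @param variant `"coacervate"` or `"monomer"`.
#' @param q Scattering-vector grid, 1/Angstrom; default 200 log-spaced
#'   points over 0.004..0.4.
#' @param noise Relative (multiplicative Gaussian) noise level; default 2%.
#' @return `gen_saxs()`: list with `curve` (a [saxs_curve()] whose `sigma`
#'   column is the known noise level) and `truth`.
#' @export
#' @examples
#' synth <- gen_saxs(seed = 1)
#' fit_saxs(synth$curve, "coacervate", synth$truth)
gen_saxs <- function(seed = 1, truth = NULL,
                     variant = c("coacervate", "monomer"),
                     q = 10^seq(log10(0.004), log10(0.4), length.out = 200),
                     noise = 0.02) {
  variant <- match.arg(variant)
  stopifnot(noise >= 0)
  if (is.null(truth)) {
    truth <- if (variant == "coacervate") {
      saxs_params(rg = 9.23, nu = 0.4, coil_scale = 1,
                  porod_amplitude = 1e-8, porod_exponent = 4,
                  background = 0.01)
    } else {
      saxs_params(rg = 9.23, nu = 0.4, coil_scale = 1, background = 0.01,
                  peak_amplitude = 0.5, peak_q0 = 0.1, peak_xi = 30)
    }
  }
  model <- composite_intensity(q, truth, variant)
  intensity <- if (noise > 0) {
    with_seed(seed, model * (1 + stats::rnorm(length(q), sd = noise)))
  } else model
  sigma <- if (noise > 0) noise * model else NULL
  list(curve = saxs_curve(q, intensity, sigma), truth = truth,
       variant = variant)
}

#' @rdname synthetic_data
#' @param mean_diameter_um Intensity-weighted mean droplet diameter of the
#'   generated log-normal ensemble, um.
#' @param sigma_g Geometric standard deviation of the log-normal ensemble.
#' @param inst A [dls_instrument()].
#' @param lag_s Lag-time grid, s.
#' @param beta Coherence factor.
#' @param noise_sd Additive correlogram noise.
#' @return `gen_dls()`: list with `correlogram` and `truth` (a
#'   [size_distribution()] whose intensity-weighted mean diameter equals
#'   `mean_diameter_um` exactly).
#' @export
gen_dls <- function(seed = 1, mean_diameter_um = 1.3, sigma_g = 1.1,
                    inst = dls_instrument(),
                    lag_s = 10^seq(-5, 3, length.out = 240),
                    beta = 0.9, noise_sd = 1e-3) {
  stopifnot(mean_diameter_um > 0, sigma_g >= 1)
  target_rh <- mean_diameter_um * 1e3 / 2      # nm
  if (sigma_g == 1) {
    truth <- size_distribution(target_rh, 1)
  } else {
    s <- log(sigma_g)
    grid <- exp(seq(log(target_rh) - 4 * s, log(target_rh) + 4 * s,
                    length.out = 101))
    w <- stats::dlnorm(grid, meanlog = log(target_rh) - s^2 / 2, sdlog = s)
    grid <- grid * target_rh / sum(grid * w / sum(w))  # pin the mean exactly
    truth <- size_distribution(grid, w)
  }
  corr <- simulate_g2(truth, inst, lag_s, beta, noise_sd, seed = seed)
  list(correlogram = corr, truth = truth)
}

#' @rdname synthetic_data
#' @param sequence Peptide sequence for the titration.
#' @param peptide_conc Peptide concentration, mol/L.
#' @param pka_set Ground-truth pKa table.
#' @param base_conc NaOH concentration grid, mol/L.
#' @param ph_noise_sd pH-meter noise standard deviation.
#' @return `gen_titration()`: list with `curve` (tibble `base_conc`, `pH`)
#'   and `truth` (the pKa table used).
#' @export
gen_titration <- function(seed = 1, sequence = "WWRR", peptide_conc = 0.04,
                          pka_set = default_pka_table(),
                          base_conc = seq(0, 0.15, length.out = 40),
                          ph_noise_sd = 0) {
  curve <- titration_curve(sequence, peptide_conc, base_conc, pka_set)
  if (ph_noise_sd > 0) {
    curve$pH <- with_seed(seed,
      pmin(14, pmax(0, curve$pH + stats::rnorm(nrow(curve), sd = ph_noise_sd))))
  }
  list(curve = curve, truth = pka_set)
}

#' @rdname synthetic_data
#' @param conc Concentration grid, wt %.
#' @param pH pH grid.
#' @param boundary_intercept,boundary_slope The ground-truth phase boundary
#'   pH as a linear function of concentration:
#'   `pH* = boundary_intercept - boundary_slope * conc`.
#' @param t_max Plateau turbidity, 1/cm.
#' @param width Sigmoid width in pH units.
#' @param noise_frac Additive noise as a fraction of `t_max`.
#' @return `gen_turbidity_grid()`: list with `points` (tibble `conc`, `pH`,
#'   `turbidity`), `truth` (function conc -> boundary pH and the parameters)
#'   and `threshold` (the half-plateau turbidity at which
#'   [assemble_phase_map()] recovers the boundary).
#' @export
gen_turbidity_grid <- function(seed = 1,
                               conc = seq(0.5, 5, by = 0.5),
                               pH = seq(8, 13, by = 0.25),
                               boundary_intercept = 12.5,
                               boundary_slope = 0.3,
                               t_max = 2, width = 0.15, noise_frac = 0) {
  stopifnot(noise_frac >= 0, t_max > 0, width > 0)
  grid <- tidyr::expand_grid(conc = conc, pH = pH)
  ph_star <- boundary_intercept - boundary_slope * grid$conc
  turb <- t_max / (1 + exp(-(grid$pH - ph_star) / width))
  if (noise_frac > 0) {
    turb <- with_seed(seed,
      pmax(0, turb + stats::rnorm(length(turb), sd = noise_frac * t_max)))
  }
  grid$turbidity <- turb
  boundary <- function(c) boundary_intercept - boundary_slope * c
  list(points = grid,
       truth = list(boundary = boundary,
                    intercept = boundary_intercept, slope = boundary_slope,
                    t_max = t_max, width = width),
       threshold = t_max / 2)
}
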