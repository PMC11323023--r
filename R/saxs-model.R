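#' Generalized Gaussian coil (excluded-volume chain) form factor
#'
#' The Benoit excluded-volume chain intensity, parameterized by the radius
#' of gyration `rg` and the Flory exponent `nu`:
#' \deqn{P(q) = \frac{1}{\nu U^{1/2\nu}} \gamma(1/2\nu, U)
#'   - \frac{1}{\nu U^{1/\nu}} \gamma(1/\nu, U), \quad
#'   U = \frac{q^2 R_g^2 (2\nu+1)(2\nu+2)}{6}}
#' with \eqn{\gamma} the lower incomplete gamma function. At \eqn{\nu = 1/2}
#' this reduces exactly to the Debye function; the high-q decay goes as
#' \eqn{q^{-1/\nu}}. \eqn{I(q) = scale \cdot P(q) + background}, so
#' \eqn{I(0) = scale + background}.
#'
#' @param q Scattering vector, 1/Angstrom; vectorized.
#' @param rg Radius of gyration, Angstrom.
#' @param nu Flory exponent, in 0.2..1.
#' @param scale Forward-scattering amplitude (intensity units).
#' @param background Flat background (intensity units).
#' @return Intensity at each `q`.
#' @export
#' @examples
#' gg_coil_intensity(0.1, rg = 9.23, nu = 0.4)
gg_coil_intensity <- function(q, rg, nu, scale = 1, background = 0) {
  stopifnot(rg > 0, nu >= 0.2, nu <= 1, background >= 0)
  U <- q^2 * rg^2 * (2 * nu + 1) * (2 * nu + 2) / 6
  scale * gg_coil_pq(U, nu) + background
}

# P(U) for the excluded-volume chain; series expansion below U ~ 1e-4 to
# avoid 0/0 at q = 0
gg_coil_pq <- function(U, nu) {
  out <- numeric(length(U))
  small <- U < 1e-4
  a <- 1 / (2 * nu)
  # P = 1 - U * [2/(1+4nu)... ] ; use two-term Taylor via the exact
  # incomplete-gamma small-U limit: gamma(s,U) ~ U^s/s - U^(s+1)/(s+1)
  s1 <- a; s2 <- 2 * a
  out[small] <- (1 / nu) * (1 / s1 - U[small] / (s1 + 1)) -
    (1 / nu) * (1 / s2 - U[small] / (s2 + 1))
  u <- U[!small]
  out[!small] <- lower_inc_gamma(s1, u) / (nu * u^s1) -
    lower_inc_gamma(s2, u) / (nu * u^s2)
  out
}

lower_inc_gamma <- function(s, x) stats::pgamma(x, s) * gamma(s)

#' Porod power-law term
#'
#' \eqn{I(q) = I_s q^{-n}}. With n = 4 this is Porod scattering from the
#' sharp interfaces of discrete objects (droplets).
#'
#' @param q Scattering vector, 1/Angstrom.
#' @param porod_amplitude Amplitude \eqn{I_s}.
#' @param porod_exponent Exponent n, > 0.
#' @return Intensity at each `q`.
#' @export
porod_term <- function(q, porod_amplitude, porod_exponent = 4) {
  stopifnot(all(q > 0), porod_exponent > 0)
  porod_amplitude * q^(-porod_exponent)
}

#' Empirical correlation-peak structure factor
#'
#' \deqn{S(q) = 1 + c / (1 + (|q - q_0| \xi)^m)}
#' A generic interference peak centred at `q0` with correlation length `xi`
#' and shape exponent `m`; S(q0) = 1 + c and S tends to 1 far from the peak.
#' Used to describe the intermolecular-correlation peaks that concentrated
#' monomer solutions show near q ~ 0.1 1/Angstrom.
#'
#' @param q Scattering vector, 1/Angstrom.
#' @param peak_amplitude Peak height c above 1.
#' @param peak_q0 Peak position, 1/Angstrom.
#' @param peak_xi Correlation length, Angstrom (> 0).
#' @param peak_m Shape exponent (default 2).
#' @return Dimensionless factor at each `q`.
#' @export
peak_structure_factor <- function(q, peak_amplitude, peak_q0, peak_xi,
                                  peak_m = 2) {
  stopifnot(peak_xi > 0)
  1 + peak_amplitude / (1 + (abs(q - peak_q0) * peak_xi)^peak_m)
}

#' SAXS model parameter set
#'
#' Collects the parameters of the composite scattering model. The
#' `coacervate` variant is Porod power law + generalized Gaussian coil +
#' background; the `monomer` variant is coil x correlation-peak structure
#' factor + background.
#'
#' @param rg Radius of gyration, Angstrom.
#' @param nu Flory exponent (0.2..1).
#' @param coil_scale Coil forward-scattering amplitude.
#' @param porod_amplitude,porod_exponent Porod term (coacervate variant).
#' @param background Flat background, >= 0.
#' @param peak_amplitude,peak_q0,peak_xi,peak_m Correlation peak (monomer
#'   variant); `peak_amplitude = 0` disables it.
#' @return A named list of class `saxs_params`.
#' @export
saxs_params <- function(rg, nu = 0.5, coil_scale = 1,
                        porod_amplitude = 0, porod_exponent = 4,
                        background = 0,
                        peak_amplitude = 0, peak_q0 = 0.1, peak_xi = 30,
                        peak_m = 2) {
  p <- list(rg = rg, nu = nu, coil_scale = coil_scale,
            porod_amplitude = porod_amplitude,
            porod_exponent = porod_exponent, background = background,
            peak_amplitude = peak_amplitude, peak_q0 = peak_q0,
            peak_xi = peak_xi, peak_m = peak_m)
  stopifnot(p$rg > 0, p$nu >= 0.2, p$nu <= 1, p$porod_exponent > 0,
            p$background >= 0, p$peak_xi > 0)
  structure(p, class = "saxs_params")
}

#' Composite SAXS model intensity
#'
#' @param q Scattering vector, 1/Angstrom.
#' @param params A [saxs_params()] set.
#' @param variant `"coacervate"` (Porod + coil + background) or `"monomer"`
#'   (coil x peak structure factor + background).
#' @return Intensity at each `q`.
#' @export
#' @examples
#' p <- saxs_params(rg = 9.23, nu = 0.4, porod_amplitude = 1e-8,
#'                  background = 0.01)
#' composite_intensity(c(0.01, 0.1), p, "coacervate")
composite_intensity <- function(q, params, variant = c("coacervate", "monomer")) {
  variant <- match.arg(variant)
  coil <- gg_coil_intensity(q, params$rg, params$nu, params$coil_scale, 0)
  if (variant == "coacervate") {
    porod_term(q, params$porod_amplitude, params$porod_exponent) +
      coil + params$background
  } else {
    s <- peak_structure_factor(q, params$peak_amplitude, params$peak_q0,
                               params$peak_xi, params$peak_m)
    coil * s + params$background
  }
}
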