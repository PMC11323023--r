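#' Electrolyte environment for droplet electrostatics
#'
#' Bundles temperature, relative permittivity and the Debye screening length.
#' Either `debye_length_nm` or `ionic_strength` must be given; when both are
#' given they must be mutually consistent (the Debye length is recomputed
#' from the ionic strength and compared at 1e-6 relative tolerance).
#'
#' @param debye_length_nm Debye length \eqn{\kappa^{-1}} in nm.
#' @param ionic_strength Ionic strength in mol/L (optional).
#' @param temperature Temperature in K.
#' @param epsilon Relative permittivity (dielectric constant); default 78.4,
#'   water near 298 K.
#' @return An object of class `electrolyte_env`.
#' @export
#' @examples
#' electrolyte_env(debye_length_nm = 2.42)
electrolyte_env <- function(debye_length_nm = NULL, ionic_strength = NULL,
                            temperature = 298, epsilon = 78.4) {
  stopifnot(temperature > 0, epsilon > 1)
  if (is.null(debye_length_nm) && is.null(ionic_strength)) {
    stop("supply debye_length_nm or ionic_strength", call. = FALSE)
  }
  if (!is.null(ionic_strength)) {
    stopifnot(ionic_strength > 0)
    ld <- debye_length(ionic_strength, temperature, epsilon)
    if (!is.null(debye_length_nm) &&
        abs(ld - debye_length_nm) / debye_length_nm > 1e-6) {
      stop("debye_length_nm inconsistent with ionic_strength", call. = FALSE)
    }
    debye_length_nm <- ld
  }
  stopifnot(debye_length_nm > 0)
  structure(list(
    temperature = temperature,
    epsilon = epsilon,
    debye_length_nm = debye_length_nm,
    ionic_strength = ionic_strength
  ), class = "electrolyte_env")
}

#' Debye screening length of an electrolyte
#'
#' \deqn{\kappa^{-1} = \sqrt{\varepsilon \varepsilon_0 k_B T /
#'   (2 N_A e^2 \cdot 1000 I)}}
#' for ionic strength I in mol/L.
#'
#' @param ionic_strength Ionic strength, mol/L.
#' @inheritParams electrolyte_env
#' @return Debye length in nm.
#' @export
#' @examples
#' debye_length(0.1)        # ~0.96 nm in water at 298 K
#' ionic_strength_from_debye(2.42)
debye_length <- function(ionic_strength, temperature = 298, epsilon = 78.4) {
  stopifnot(all(ionic_strength > 0))
  k <- .const
  sqrt(epsilon * k$eps0 * k$kB * temperature /
         (2 * k$`NA` * k$e^2 * 1000 * ionic_strength)) * 1e9
}

#' @rdname debye_length
#' @param debye_length_nm Debye length in nm.
#' @export
ionic_strength_from_debye <- function(debye_length_nm, temperature = 298,
                                      epsilon = 78.4) {
  stopifnot(all(debye_length_nm > 0))
  k <- .const
  epsilon * k$eps0 * k$kB * temperature /
    (2 * k$`NA` * k$e^2 * 1000 * (debye_length_nm * 1e-9)^2)
}

#' Surface charge density from zeta potential (Grahame equation)
#'
#' Converts a surface (zeta) potential into surface charge density. In
#' `linear` mode (valid at low potential) \eqn{\sigma = \varepsilon
#' \varepsilon_0 \kappa \psi_0}. In `full_1to1` mode the full Grahame
#' relation for a symmetric 1:1 electrolyte is used,
#' \eqn{\sigma = 2 \varepsilon \varepsilon_0 \kappa (k_B T / e)
#'   \sinh(e \psi_0 / 2 k_B T)},
#' which reduces to the linear form to first order as \eqn{\psi_0 \to 0}.
#'
#' @param psi0 Surface potential in V (a measured zeta potential is used
#'   directly, no slip-plane correction).
#' @param env An [electrolyte_env()].
#' @param mode `"linear"` or `"full_1to1"`.
#' @return Surface charge density in C/m^2.
#' @export
#' @examples
#' env <- electrolyte_env(debye_length_nm = 2.42)
#' grahame_surface_charge(1.1e-3, env)  # ~0.31 mC/m^2
grahame_surface_charge <- function(psi0, env, mode = c("linear", "full_1to1")) {
  mode <- match.arg(mode)
  stopifnot(inherits(env, "electrolyte_env"))
  k <- .const
  kappa <- 1 / (env$debye_length_nm * 1e-9)
  if (mode == "linear") {
    env$epsilon * k$eps0 * kappa * psi0
  } else {
    vt <- k$kB * env$temperature / k$e
    2 * env$epsilon * k$eps0 * kappa * vt * sinh(psi0 / (2 * vt))
  }
}

#' Rayleigh stability-limit charge of a droplet
#'
#' Maximum net charge a droplet of diameter `d` and interfacial tension
#' `gamma` can hold before Coulomb repulsion overcomes surface tension:
#' \deqn{q = \pi \sqrt{8 \varepsilon_0 \gamma d^3}.}
#' Algebraically equivalent to \eqn{q = \sigma \pi d^2} with
#' \eqn{\sigma = \sqrt{8 \varepsilon_0 \gamma / d}} at the limit, so it is
#' mutually consistent with [critical_diameter()].
#'
#' @param d Droplet diameter, m.
#' @param gamma Interfacial tension, N/m.
#' @return Limit charge in C.
#' @export
#' @examples
#' rayleigh_limit_charge(1.3e-6, 1.8e-3)  # ~1.66e-15 C
rayleigh_limit_charge <- function(d, gamma) {
  stopifnot(all(d > 0), all(gamma >= 0))
  pi * sqrt(8 * .const$eps0 * gamma * d^3)
}

#' Droplet diameter at the Rayleigh stability limit
#'
#' For a droplet whose surface charge density is `sigma`, the diameter at
#' which that charge sits exactly at the Rayleigh limit:
#' \deqn{d = 8 \varepsilon_0 \gamma / \sigma^2.}
#'
#' @param sigma Surface charge density, C/m^2 (nonzero).
#' @param gamma Interfacial tension, N/m.
#' @return Diameter in m.
#' @export
#' @examples
#' critical_diameter(0.31e-3, 1.8e-3)  # ~1.3e-6 m
critical_diameter <- function(sigma, gamma) {
  if (any(sigma == 0)) stop("sigma must be nonzero (diameter unbounded)", call. = FALSE)
  stopifnot(all(gamma >= 0))
  8 * .const$eps0 * gamma / sigma^2
}

#' Interfacial tension from droplet size and surface charge density
#'
#' Inverts the Rayleigh-limit relation: assuming the measured droplets sit
#' at the stability limit, \eqn{\gamma = d \sigma^2 / (8 \varepsilon_0)}.
#'
#' @param d Droplet diameter, m.
#' @param sigma Surface charge density, C/m^2.
#' @return Interfacial tension in N/m.
#' @export
#' @examples
#' interfacial_tension(1.3e-6, 0.31e-3)  # ~1.8e-3 N/m
interfacial_tension <- function(d, sigma) {
  if (any(d <= 0)) stop("diameter must be positive", call. = FALSE)
  d * sigma^2 / (8 * .const$eps0)
}

#' Interfacial tension pipeline from droplet measurements
#'
#' The full measurement-to-tension chain: zeta potential to surface charge
#' density (Grahame), then droplet diameter + charge density to interfacial
#' tension (Rayleigh limit), then the limit charge itself. Inputs are echoed
#' in the result for provenance.
#'
#' @param diameter_um Droplet diameter(s), micrometres.
#' @param zeta_mV Zeta potential(s), mV, used directly as the surface
#'   potential.
#' @param env An [electrolyte_env()].
#' @param grahame `"linear"` or `"full_1to1"`, passed to
#'   [grahame_surface_charge()].
#' @return A tibble with one row per measurement: the echoed inputs plus
#'   `sigma_mC_m2` (surface charge density, mC/m^2), `gamma_mN_m`
#'   (interfacial tension, mN/m) and `limit_charge_C` (Rayleigh limit
#'   charge, C).
#' @export
#' @examples
#' tension_from_measurements(1.3, 1.1, electrolyte_env(debye_length_nm = 2.42))
tension_from_measurements <- function(diameter_um, zeta_mV,
                                      env = electrolyte_env(debye_length_nm = 2.42),
                                      grahame = c("linear", "full_1to1")) {
  grahame <- match.arg(grahame)
  stopifnot(all(diameter_um > 0))
  n <- max(length(diameter_um), length(zeta_mV))
  d <- rep_len(diameter_um, n) * 1e-6
  psi0 <- rep_len(zeta_mV, n) * 1e-3
  sigma <- grahame_surface_charge(psi0, env, grahame)
  gamma <- interfacial_tension(d, sigma)
  q <- sign(sigma) * rayleigh_limit_charge(d, gamma)
  tibble::tibble(
    diameter_um = d * 1e6,
    zeta_mV = psi0 * 1e3,
    debye_nm = env$debye_length_nm,
    epsilon = env$epsilon,
    temperature_K = env$temperature,
    grahame_mode = grahame,
    sigma_mC_m2 = sigma * 1e3,
    gamma_mN_m = gamma * 1e3,
    limit_charge_C = q
  )
}
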