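#' Convert weight percent to molarity
#'
#' Assumes a solution density of 1 g/mL, so wt % is g per 100 mL and
#' molarity is `10 * wt_pct / molar_mass` mol/L.
#'
#' @param wt_pct Concentration in weight percent, > 0.
#' @param molar_mass Molar mass in Da (g/mol), > 0.
#' @return Molar concentration, mol/L.
#' @export
#' @examples
#' molarity_from_wt_pct(3, 360.42)
molarity_from_wt_pct <- function(wt_pct, molar_mass) {
  stopifnot(all(wt_pct > 0), all(molar_mass > 0))
  10 * wt_pct / molar_mass
}

#' Mixture specification for a peptide + charged partner formulation
#'
#' Bundles the quantities needed to compute a complex-coacervation
#' composition at a given charge ratio: the peptide's molar mass and assumed
#' integer charge, the partner's molar mass and charge (e.g. ATP disodium
#' salt, 551.14 Da, charge -2), the peptide concentration, and the
#' peptide:partner charge ratio (1 for 1:1, 0.5 for 1:0.5).
#'
#' @param peptide_molar_mass Peptide molar mass, Da.
#' @param peptide_charge Assumed integer peptide charge, > 0.
#' @param peptide_wt_pct Peptide concentration, wt %.
#' @param partner_molar_mass Partner molar mass, Da. Default is the ATP
#'   disodium salt; use 507.18 for the free acid.
#' @param partner_charge Assumed integer partner charge, < 0 (ATP: -2).
#' @param charge_ratio Partner:peptide charge-equivalent ratio factor;
#'   1 gives charge-matched (1:1), 0.5 gives half the partner (1:0.5).
#' @return An object of class `mixture_spec` (a list).
#' @export
#' @examples
#' mixture_spec(360.42, 1, 3)  # WR : ATP at 1:1
mixture_spec <- function(peptide_molar_mass, peptide_charge, peptide_wt_pct,
                         partner_molar_mass = 551.14, partner_charge = -2L,
                         charge_ratio = 1) {
  stopifnot(peptide_molar_mass > 0, partner_molar_mass > 0,
            peptide_charge > 0, partner_charge < 0,
            peptide_wt_pct > 0, peptide_wt_pct < 100,
            charge_ratio > 0)
  structure(list(
    peptide_molar_mass = peptide_molar_mass,
    peptide_charge = as.integer(peptide_charge),
    peptide_wt_pct = peptide_wt_pct,
    partner_molar_mass = partner_molar_mass,
    partner_charge = as.integer(partner_charge),
    charge_ratio = charge_ratio
  ), class = "mixture_spec")
}

#' Partner weight percent matching a target charge ratio
#'
#' Computes the partner (e.g. ATP) concentration whose negative charge
#' equivalents balance the peptide's positive equivalents at the requested
#' ratio: partner molarity = peptide molarity x peptide charge x ratio /
#' |partner charge|, converted back to wt % and rounded half-up to one
#' decimal (the convention used when reporting compositions).
#'
#' @param m A `mixture_spec` from [mixture_spec()].
#' @param round Round the result to 1 decimal (default `TRUE`).
#' @return Partner concentration, wt %.
#' @export
#' @examples
#' partner_wt_pct_for_charge_ratio(mixture_spec(360.42, 1, 3))  # 2.3
#' partner_wt_pct_for_charge_ratio(mixture_spec(702.82, 2, 3))  # 2.4
partner_wt_pct_for_charge_ratio <- function(m, round = TRUE) {
  stopifnot(inherits(m, "mixture_spec"))
  if (m$partner_charge == 0) stop("partner charge must be nonzero", call. = FALSE)
  pep_mol <- molarity_from_wt_pct(m$peptide_wt_pct, m$peptide_molar_mass)
  partner_mol <- pep_mol * m$peptide_charge * m$charge_ratio / abs(m$partner_charge)
  wt <- partner_mol * m$partner_molar_mass / 10
  if (round) round_half_up(wt, 1) else wt
}

#' Turbidity from absorbance
#'
#' Attenuation per unit path length from the decadic absorbance at 500 nm:
#' \eqn{T = \ln(10) A / L}. 500 nm is chosen because the peptides have no
#' intrinsic absorbance there, so all attenuation is scattering by droplets.
#'
#' @param A Absorbance (dimensionless), >= 0; vectorized.
#' @param L Optical path length, cm.
#' @return Turbidity in 1/cm.
#' @export
#' @examples
#' turbidity_from_absorbance(1, 1)  # ln 10 = 2.3026
turbidity_from_absorbance <- function(A, L) {
  stopifnot(all(A >= 0))
  if (any(L <= 0)) stop("path length must be positive", call. = FALSE)
  log(10) * A / L
}

#' Assemble a phase map from turbidity measurements
#'
#' Flags each (concentration, pH) grid point as phase separated when its
#' turbidity meets or exceeds `threshold` (inclusive boundary).
#'
#' @param points A data frame with columns `conc`, `pH`, and either
#'   `turbidity` or both `A500` and `path_cm` (converted via
#'   [turbidity_from_absorbance()]).
#' @param threshold Turbidity threshold, 1/cm.
#' @return A tibble of class `phase_map` with columns `conc`, `pH`,
#'   `turbidity`, `llps` (logical).
#' @export
assemble_phase_map <- function(points, threshold) {
  stopifnot(is.data.frame(points), nrow(points) > 0, threshold >= 0)
  pts <- tibble::as_tibble(points)
  if (!"turbidity" %in% names(pts)) {
    if (!all(c("A500", "path_cm") %in% names(pts))) {
      stop("points need a turbidity column or A500 + path_cm", call. = FALSE)
    }
    pts$turbidity <- turbidity_from_absorbance(pts$A500, pts$path_cm)
  }
  if (!all(c("conc", "pH") %in% names(pts))) {
    stop("points need conc and pH columns", call. = FALSE)
  }
  if (anyDuplicated(pts[c("conc", "pH")]) > 0) {
    stop("duplicate (conc, pH) grid coordinates", call. = FALSE)
  }
  out <- dplyr::mutate(
    pts[c("conc", "pH", "turbidity")],
    llps = .data$turbidity >= threshold
  )
  out <- dplyr::arrange(out, .data$conc, .data$pH)
  attr(out, "threshold") <- threshold
  class(out) <- c("phase_map", class(out))
  out
}

#' Write a phase map to CSV
#'
#' @param pm A `phase_map` from [assemble_phase_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phase_map_csv <- function(pm, path) {
  readr::write_csv(tibble::as_tibble(pm), path)
  invisible(path)
}

#' Read a turbidity-grid CSV
#'
#' Columns: `sample` (optional), `conc`, `pH`, `A500`, `path_cm`.
#'
#' @param path CSV path.
#' @return A tibble suitable for [assemble_phase_map()].
#' @export
read_turbidity_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("conc", "pH", "A500", "path_cm")
  if (!all(need %in% names(tab))) {
    stop("turbidity CSV must have columns conc, pH, A500, path_cm", call. = FALSE)
  }
  tibble::as_tibble(tab)
}
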