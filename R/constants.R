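#' Physical constants used throughout the package
#'
#' CODATA 2018 values, SI units. Centralized so every module (electrostatics,
#' DLS, titration) draws on the same table.
#'
#' @return A named list with elements `kB` (Boltzmann constant, J/K), `e`
#'   (elementary charge, C), `NA` (Avogadro constant, 1/mol), `eps0` (vacuum
#'   permittivity, F/m), `Kw` (water ion product at 25 degrees C).
#' @export
#' @examples
#' physical_constants()$eps0
physical_constants <- function() {
  list(
    kB   = 1.380649e-23,
    e    = 1.602176634e-19,
    "NA" = 6.02214076e23,
    eps0 = 8.8541878128e-12,
    Kw   = 1e-14
  )
}

.const <- physical_constants()

# round-half-up to `digits` decimals; base round() is round-half-even and
# formulation wt% values are reported the way figure captions print them
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
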