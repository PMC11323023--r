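#' DLS instrument description
#'
#' Geometry and solvent parameters of a dynamic light scattering setup.
#' Defaults describe a He-Ne goniometer system (632.8 nm, 90 degrees) with
#' water at 298 K.
#'
#' @param wavelength_nm Vacuum laser wavelength, nm.
#' @param angle_deg Scattering angle, degrees (0, 180).
#' @param n_medium Refractive index of the medium.
#' @param temperature Temperature, K.
#' @param viscosity Solvent viscosity, Pa s.
#' @return An object of class `dls_instrument`.
#' @export
#' @examples
#' dls_instrument()
dls_instrument <- function(wavelength_nm = 632.8, angle_deg = 90,
                           n_medium = 1.33, temperature = 298,
                           viscosity = 0.89e-3) {
  stopifnot(wavelength_nm > 0, angle_deg > 0, angle_deg < 180,
            n_medium > 0, temperature > 0, viscosity > 0)
  structure(list(
    wavelength_nm = wavelength_nm, angle_deg = angle_deg,
    n_medium = n_medium, temperature = temperature, viscosity = viscosity
  ), class = "dls_instrument")
}

#' Scattering vector magnitude
#'
#' \eqn{q = 4 \pi n \sin(\theta/2) / \lambda}.
#'
#' @param inst A [dls_instrument()].
#' @return q in 1/m.
#' @export
#' @examples
#' scattering_vector(dls_instrument())  # ~1.87e7 1/m
scattering_vector <- function(inst) {
  stopifnot(inherits(inst, "dls_instrument"))
  4 * pi * inst$n_medium * sin(inst$angle_deg * pi / 360) /
    (inst$wavelength_nm * 1e-9)
}

#' Stokes-Einstein diffusion coefficient
#'
#' \eqn{D = k_B T / (6 \pi \eta R_h)}.
#'
#' @param rh Hydrodynamic radius, m; vectorized.
#' @param temperature Temperature, K.
#' @param viscosity Viscosity, Pa s.
#' @return D in m^2/s.
#' @export
#' @examples
#' diffusion_coefficient(1e-9)  # ~2.45e-10 m^2/s
diffusion_coefficient <- function(rh, temperature = 298, viscosity = 0.89e-3) {
  stopifnot(all(rh > 0), temperature > 0, viscosity > 0)
  .const$kB * temperature / (6 * pi * viscosity * rh)
}

#' Hydrodynamic-radius size distribution
#'
#' Intensity-basis weights on a radius grid; weights are normalized to sum
#' to 1.
#'
#' @param rh_nm Hydrodynamic radii, nm, increasing.
#' @param weight Non-negative intensity weights.
#' @return A tibble of class `size_distribution` with columns `rh_nm`,
#'   `weight` (normalized).
#' @export
size_distribution <- function(rh_nm, weight) {
  stopifnot(length(rh_nm) == length(weight), all(rh_nm > 0),
            all(weight >= 0), sum(weight) > 0, !is.unsorted(rh_nm))
  out <- tibble::tibble(rh_nm = rh_nm, weight = weight / sum(weight))
  class(out) <- c("size_distribution", class(out))
  out
}

#' Intensity-weighted mean droplet diameter
#'
#' \eqn{\bar d = 2 \sum_i w_i R_{h,i}} over a normalized intensity-basis
#' distribution.
#'
#' @param dist A [size_distribution()].
#' @return Mean diameter in nm.
#' @export
#' @examples
#' intensity_weighted_mean_diameter(size_distribution(650, 1))  # 1300
intensity_weighted_mean_diameter <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  2 * sum(dist$weight * dist$rh_nm) / sum(dist$weight)
}

#' Construct a correlogram
#'
#' @param lag_s Lag times, s, strictly increasing, > 0.
#' @param g2_minus_1 Intensity autocorrelation minus baseline.
#' @param beta Coherence (intercept) factor.
#' @return A tibble of class `correlogram` with attribute `beta`.
#' @export
correlogram <- function(lag_s, g2_minus_1, beta = 1) {
  stopifnot(all(lag_s > 0), !is.unsorted(lag_s, strictly = TRUE),
            length(lag_s) == length(g2_minus_1), beta > 0)
  out <- tibble::tibble(lag_s = lag_s, g2_minus_1 = g2_minus_1)
  attr(out, "beta") <- beta
  class(out) <- c("correlogram", class(out))
  out
}

#' Simulate a DLS correlogram (Siegert relation)
#'
#' Field autocorrelation \eqn{g_1(\tau) = \sum_i w_i e^{-D_i q^2 \tau}} over
#' the distribution, then \eqn{g_2 - 1 = \beta g_1^2} plus additive Gaussian
#' noise.
#'
#' @param dist A [size_distribution()] (intensity basis).
#' @param inst A [dls_instrument()].
#' @param lag_s Lag times, s.
#' @param beta Coherence factor.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Optional integer seed for the noise.
#' @return A `correlogram`.
#' @export
simulate_g2 <- function(dist, inst = dls_instrument(),
                        lag_s = 10^seq(-6, 3, length.out = 200),
                        beta = 1, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(dist, "size_distribution"), nrow(dist) > 0)
  g1 <- g1_from_distribution(dist, inst, lag_s)
  y <- beta * g1^2
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    y <- y + stats::rnorm(length(y), sd = noise_sd)
  }
  correlogram(lag_s, y, beta)
}

g1_from_distribution <- function(dist, inst, lag_s) {
  q <- scattering_vector(inst)
  D <- diffusion_coefficient(dist$rh_nm * 1e-9, inst$temperature, inst$viscosity)
  K <- exp(-outer(lag_s, D * q^2))
  as.numeric(K %*% (dist$weight / sum(dist$weight)))
}

#' Invert a correlogram to a size distribution (regularized NNLS)
#'
#' CONTIN-style constrained regularized inversion: solves
#' \deqn{\min_{w \ge 0} \| K w - g_1 \|^2 + \alpha^2 \| L_2 w \|^2}
#' where \eqn{K_{ij} = e^{-D_j q^2 \tau_i}} is the exponential kernel on a
#' log-spaced radius grid and \eqn{L_2} is the second-difference operator
#' (smoothness penalty). \eqn{g_1} is recovered by a sign-preserving Siegert
#' inversion, \eqn{g_1 = \mathrm{sign}(y)\sqrt{|y|}} with
#' \eqn{y = (g_2 - 1)/\beta}: keeping the sign of baseline noise avoids the
#' positive tail bias that a square root of the clipped correlogram would
#' introduce (which otherwise inflates the large-radius end of the
#' recovered distribution). The solution is normalized to an
#' intensity-basis distribution.
#'
#' `alpha = "auto"` picks the regularization weight by a noise-floor
#' discrepancy rule: the largest alpha on a log-spaced grid whose residual
#' norm stays within a factor 1.002 of the essentially unregularized
#' residual (which is dominated by the correlogram's baseline noise). This
#' keeps the fit at the noise floor while taking as much smoothing as the
#' data permit; it is better behaved for this kernel than L-curve corner
#' detection, whose residual branch is almost flat under non-negativity
#' constraints. Pass a numeric `alpha` to override.
#'
#' @param corr A [correlogram()].
#' @param inst A [dls_instrument()].
#' @param rh_grid_nm Radius grid, nm; default 60 log-spaced points over
#'   1 nm..10 um.
#' @param alpha Regularization weight >= 0, or `"auto"`.
#' @return A `size_distribution` with attributes `alpha`, `residual_norm`,
#'   `roughness` (the seminorm \eqn{\|L_2 w\|}), and `ill_conditioned`
#'   (TRUE when inverted without regularization).
#' @export
invert_g2 <- function(corr, inst = dls_instrument(),
                      rh_grid_nm = 10^seq(0, 4, length.out = 60),
                      alpha = "auto") {
  stopifnot(inherits(corr, "correlogram"))
  beta <- attr(corr, "beta")
  if (is.null(beta)) beta <- 1
  y <- corr$g2_minus_1 / beta
  g1 <- sign(y) * sqrt(abs(y))
  q <- scattering_vector(inst)
  D <- diffusion_coefficient(rh_grid_nm * 1e-9, inst$temperature, inst$viscosity)
  K <- exp(-outer(corr$lag_s, D * q^2))
  n <- length(rh_grid_nm)
  L <- second_difference_matrix(n)
  if (identical(alpha, "auto")) {
    alpha <- auto_alpha(K, g1, L)
  }
  stopifnot(is.numeric(alpha), alpha >= 0)
  w <- reg_nnls(K, g1, L, alpha)
  if (sum(w) <= 0) w <- rep(1 / n, n)   # degenerate input: flat fallback
  out <- size_distribution(rh_grid_nm, w)
  attr(out, "alpha") <- alpha
  attr(out, "residual_norm") <- sqrt(sum((K %*% w - g1)^2))
  attr(out, "roughness") <- sqrt(sum((L %*% (w / sum(w)))^2))
  attr(out, "ill_conditioned") <- alpha == 0
  if (alpha == 0) {
    warning("inverting the exponential kernel without regularization is ill-conditioned",
            call. = FALSE)
  }
  out
}

second_difference_matrix <- function(n) {
  if (n < 3) return(matrix(0, 0, n))
  L <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) L[i, i:(i + 2)] <- c(1, -2, 1)
  L
}

reg_nnls <- function(K, g1, L, alpha) {
  if (alpha > 0 && nrow(L) > 0) {
    C <- rbind(K, alpha * L)
    d <- c(g1, rep(0, nrow(L)))
  } else {
    C <- K; d <- g1
  }
  pracma::lsqnonneg(C, d)$x
}

# noise-floor discrepancy rule: largest alpha whose data misfit stays
# within `tau` of the smallest-alpha misfit (the baseline-noise floor)
auto_alpha <- function(K, g1, L, alphas = 10^seq(-4, 2, length.out = 15),
                       tau = 1.002) {
  res <- vapply(alphas, function(a) {
    w <- reg_nnls(K, g1, L, a)
    sqrt(sum((K %*% w - g1)^2))
  }, numeric(1))
  alphas[max(which(res <= tau * res[1]))]
}

#' Read a correlogram from 2-column ASCII
#'
#' Columns: lag time (s), g2 - 1; `#` comments skipped. The coherence
#' factor can be annotated as a comment `# beta = 0.9`.
#'
#' @param path File path.
#' @param beta Coherence factor; if `NULL`, taken from a `# beta =` comment
#'   or defaulting to 1.
#' @return A `correlogram`.
#' @export
read_correlogram_ascii <- function(path, beta = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (is.null(beta)) {
    bl <- grep("^\\s*#\\s*beta\\s*=", lines, value = TRUE)
    beta <- if (length(bl) > 0) as.numeric(sub(".*=\\s*", "", bl[1])) else 1
  }
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) stop("no data rows in ", path, call. = FALSE)
  m <- do.call(rbind, lapply(keep, function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[[:space:],]+")[[1]]))
    if (length(vals) < 2 || anyNA(vals[1:2])) {
      stop(sprintf("line %d: expected 2 numeric columns", i), call. = FALSE)
    }
    vals[1:2]
  }))
  m <- m[order(m[, 1]), , drop = FALSE]
  correlogram(m[, 1], m[, 2], beta)
}

#' Write a correlogram to 2-column ASCII
#'
#' @param corr A `correlogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlogram_ascii <- function(corr, path) {
  writeLines(c(
    sprintf("# beta = %.6g", attr(corr, "beta")),
    "# lag_s g2_minus_1",
    paste(format(corr$lag_s, digits = 10, scientific = TRUE, trim = TRUE),
          format(corr$g2_minus_1, digits = 10, scientific = TRUE, trim = TRUE))
  ), path)
  invisible(path)
}

#' Write a size distribution to CSV
#'
#' @param dist A `size_distribution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_size_distribution_csv <- function(dist, path) {
  readr::write_csv(tibble::as_tibble(dist), path)
  invisible(path)
}
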