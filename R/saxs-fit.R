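#' Construct a SAXS curve
#'
#' @param q Scattering vector, 1/Angstrom, strictly increasing, > 0.
#' @param intensity Measured intensity (arbitrary units), finite.
#' @param sigma Optional intensity uncertainties (same units).
#' @return A tibble of class `saxs_curve` with columns `q`, `intensity` and
#'   optionally `sigma`.
#' @export
saxs_curve <- function(q, intensity, sigma = NULL) {
  stopifnot(length(q) >= 10, length(intensity) == length(q),
            all(q > 0), all(is.finite(intensity)), !is.unsorted(q, strictly = TRUE))
  out <- tibble::tibble(q = q, intensity = intensity)
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(q), all(sigma > 0))
    out$sigma <- sigma
  }
  class(out) <- c("saxs_curve", class(out))
  out
}

#' Read a 1-D SAXS curve from ASCII
#'
#' Parses 2- or 3-column whitespace- or comma-separated text (q, I
#' \[, sigma\]), skipping blank lines and `#` comments. q must be positive;
#' rows are sorted to ascending q.
#'
#' @param path Path to the file.
#' @return A `saxs_curve` tibble.
#' @export
read_saxs_ascii <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) stop("no data rows in ", path, call. = FALSE)
  rows <- lapply(keep, function(i) {
    fields <- strsplit(trimws(lines[i]), "[[:space:],]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2 || anyNA(vals)) {
      stop(sprintf("line %d: expected 2-3 numeric columns", i), call. = FALSE)
    }
    if (vals[1] <= 0) {
      stop(sprintf("line %d: non-positive q value", i), call. = FALSE)
    }
    vals[1:min(3, length(vals))]
  })
  ncol <- min(lengths(rows))
  m <- do.call(rbind, lapply(rows, function(r) r[1:ncol]))
  m <- m[order(m[, 1]), , drop = FALSE]
  saxs_curve(m[, 1], m[, 2], if (ncol >= 3) m[, 3] else NULL)
}

#' Write a SAXS curve to 3-column ASCII
#'
#' @param curve A `saxs_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_saxs_ascii <- function(curve, path) {
  header <- if ("sigma" %in% names(curve)) "# q I sigma" else "# q I"
  cols <- intersect(c("q", "intensity", "sigma"), names(curve))
  body <- do.call(paste, c(lapply(cols, function(cn) {
    format(curve[[cn]], digits = 10, scientific = TRUE, trim = TRUE)
  }), sep = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

# free parameters per variant, in fitting order
saxs_free_params <- function(variant) {
  if (variant == "coacervate") {
    c("porod_amplitude", "porod_exponent", "coil_scale", "rg", "nu", "background")
  } else {
    c("coil_scale", "rg", "nu", "background",
      "peak_amplitude", "peak_q0", "peak_xi", "peak_m")
  }
}

saxs_bounds <- function(names) {
  lower <- c(porod_amplitude = 0, porod_exponent = 0.5, coil_scale = 0,
             rg = 0.5, nu = 0.2, background = 0,
             peak_amplitude = 0, peak_q0 = 1e-3, peak_xi = 1, peak_m = 0.5)
  upper <- c(porod_amplitude = Inf, porod_exponent = 6, coil_scale = Inf,
             rg = 1e4, nu = 1, background = Inf,
             peak_amplitude = Inf, peak_q0 = 10, peak_xi = 1e4, peak_m = 8)
  list(lower = lower[names], upper = upper[names])
}

#' Fit the composite SAXS model to a measured curve
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt with box bounds)
#' of [composite_intensity()] against a [saxs_curve()]. Residuals are
#' weighted by 1/sigma when the curve carries uncertainties, otherwise
#' unweighted. Parameters named in `fixed` are held at their `init` values
#' (the Porod exponent is fixed at 4 by default for the coacervate variant,
#' matching Porod scattering from sharp droplet interfaces; release it by
#' passing `fixed` without `"porod_exponent"`). Non-convergence is flagged
#' in the result, not raised.
#'
#' @param curve A `saxs_curve`.
#' @param variant `"coacervate"` or `"monomer"`.
#' @param init A [saxs_params()] set of initial values.
#' @param fixed Character vector of parameter names to hold fixed. Default:
#'   `"porod_exponent"` (coacervate), `"peak_m"` (monomer).
#' @return An object of class `saxs_fit`: list with `params` (fitted
#'   [saxs_params()]), `stderr` (named, NA for fixed parameters),
#'   `reduced_chisq`, `converged`, `variant`, `fixed`, `curve`, and
#'   `fitted` (model intensities at the data q).
#' @export
#' @examples
#' truth <- saxs_params(rg = 9.23, nu = 0.4, porod_amplitude = 1e-8,
#'                      background = 0.01)
#' q <- exp(seq(log(0.004), log(0.4), length.out = 100))
#' crv <- saxs_curve(q, composite_intensity(q, truth, "coacervate"))
#' fit <- fit_saxs(crv, "coacervate", truth)
#' tidy(fit)
fit_saxs <- function(curve, variant = c("coacervate", "monomer"), init,
                     fixed = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(curve, "saxs_curve"), inherits(init, "saxs_params"))
  if (is.null(fixed)) {
    fixed <- if (variant == "coacervate") "porod_exponent" else "peak_m"
  }
  all_names <- saxs_free_params(variant)
  free <- setdiff(all_names, fixed)
  start <- unlist(init[free])
  b <- saxs_bounds(free)
  start <- pmin(pmax(start, b$lower), b$upper)
  w <- if ("sigma" %in% names(curve)) 1 / curve$sigma else rep(1, nrow(curve))

  make_params <- function(x) {
    p <- init
    p[free] <- as.list(x)
    p
  }
  resid_fun <- function(x) {
    model <- composite_intensity(curve$q, make_params(x), variant)
    (model - curve$intensity) * w
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = b$lower, upper = b$upper, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  est <- stats::setNames(as.numeric(fit$par), free)
  params <- make_params(est)
  n_free <- length(free)
  dof <- max(nrow(curve) - n_free, 1)
  red_chisq <- sum(resid_fun(est)^2) / dof
  stderr <- rep(NA_real_, length(all_names))
  names(stderr) <- all_names
  se <- tryCatch({
    # Gauss-Newton covariance; NA if the hessian is singular (e.g. a
    # parameter pinned at a bound)
    sqrt(pmax(diag(chol2inv(chol(fit$hessian))) * red_chisq, 0))
  }, error = function(e) rep(NA_real_, n_free))
  stderr[free] <- se
  converged <- fit$info %in% 1:4
  structure(list(
    params = params, stderr = stderr, reduced_chisq = red_chisq,
    converged = converged, variant = variant, fixed = fixed,
    curve = curve,
    fitted = composite_intensity(curve$q, params, variant),
    info = fit$info, message = fit$message
  ), class = "saxs_fit")
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat("<saxs_fit> variant:", x$variant,
      "| reduced chi-square:", signif(x$reduced_chisq, 4),
      "| converged:", x$converged, "\n")
  print(tidy(x))
  invisible(x)
}
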