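#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a SAXS fit
#'
#' One row per model parameter with estimate, standard error (NA for fixed
#' parameters) and whether the parameter was held fixed.
#'
#' @param x A `saxs_fit` from [fit_saxs()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`, `fixed`.
#' @method tidy saxs_fit
#' @export
tidy.saxs_fit <- function(x, ...) {
  terms <- saxs_free_params(x$variant)
  tibble::tibble(
    term = terms,
    estimate = unlist(x$params[terms]),
    std.error = unname(x$stderr[terms]),
    fixed = terms %in% x$fixed
  )
}

#' @rdname tidy.saxs_fit
#' @return `glance()`: a one-row tibble with `variant`, `reduced.chisq`,
#'   `converged`, `nobs`, `df.residual`.
#' @method glance saxs_fit
#' @export
glance.saxs_fit <- function(x, ...) {
  n_free <- length(setdiff(saxs_free_params(x$variant), x$fixed))
  tibble::tibble(
    variant = x$variant,
    reduced.chisq = x$reduced_chisq,
    converged = x$converged,
    nobs = nrow(x$curve),
    df.residual = nrow(x$curve) - n_free
  )
}

#' Tidy a size distribution
#'
#' @param x A `size_distribution` from [invert_g2()] or
#'   [size_distribution()].
#' @param ... Unused.
#' @return The distribution as a plain tibble (`rh_nm`, `weight`).
#' @method tidy size_distribution
#' @export
tidy.size_distribution <- function(x, ...) {
  tibble::tibble(rh_nm = x$rh_nm, weight = x$weight)
}

#' @rdname tidy.size_distribution
#' @return `glance()`: one row with `mean_diameter_nm`, `alpha`,
#'   `residual_norm`, `roughness`.
#' @method glance size_distribution
#' @export
glance.size_distribution <- function(x, ...) {
  tibble::tibble(
    mean_diameter_nm = intensity_weighted_mean_diameter(x),
    alpha = attr(x, "alpha") %||% NA_real_,
    residual_norm = attr(x, "residual_norm") %||% NA_real_,
    roughness = attr(x, "roughness") %||% NA_real_
  )
}

#' Plot a SAXS fit
#'
#' Log-log plot of the measured curve (points) with the fitted composite
#' model (line).
#'
#' @param object A `saxs_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot saxs_fit
#' @export
autoplot.saxs_fit <- function(object, ...) {
  df <- tibble::tibble(q = object$curve$q, intensity = object$curve$intensity,
                       fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity), shape = 1,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q) (a.u.)",
                  title = paste("Composite SAXS fit:", object$variant))
}

#' Plot a recovered size distribution
#'
#' @param object A `size_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot size_distribution
#' @export
autoplot.size_distribution <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$rh_nm, y = .data$weight)) +
    ggplot2::geom_col(width = 0.05) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(R[h] ~ (nm)), y = "intensity weight")
}

#' Plot a turbidity phase map
#'
#' Tile map of turbidity over the (concentration, pH) grid with the
#' phase-separated region outlined by the flag.
#'
#' @param object A `phase_map` from [assemble_phase_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phase_map
#' @export
autoplot.phase_map <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$conc, y = .data$pH)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$turbidity)) +
    ggplot2::geom_point(data = function(d) d[d$llps, ], shape = 4, size = 1) +
    ggplot2::labs(x = "concentration (wt %)", y = "pH",
                  fill = expression(T ~ (cm^-1)),
                  caption = "crosses: turbidity at or above the LLPS threshold")
}

#' Plot charge speciation versus pH
#'
#' @param p A peptide (sequence or `peptide_spec`).
#' @param pH pH grid.
#' @param pka_set pKa table.
#' @return A ggplot object of charge-state fractions versus pH.
#' @export
plot_speciation <- function(p, pH = seq(0, 14, by = 0.1),
                            pka_set = default_pka_table()) {
  sp <- speciation(p, pH, pka_set)
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$pH, y = .data$fraction,
                                   colour = factor(.data$charge))) +
    ggplot2::geom_line() +
    ggplot2::labs(colour = "net charge", y = "species fraction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
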