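#' Plot a fitted binodal curve with its data and phase regions
#'
#' Shows the fitted binodal curve over the data points; the area above the
#' curve is the two-phase region where an aqueous two-phase system forms.
#'
#' @param object A `binodal_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot binodal_fit
#' @export
autoplot.binodal_fit <- function(object, ...) {
  grid <- tibble::tibble(w2 = seq(min(object$data$w2), max(object$data$w2),
                                  length.out = 200))
  grid$w1 <- eval_binodal(grid$w2, object$coefficients)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$w2, y = .data$w1)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Salt mass fraction w2",
                  y = "Alcohol mass fraction w1",
                  title = "Binodal curve (two-phase region above)") +
    ggplot2::theme_minimal()
}

#' Plot an effective-diffusivity fit against the observed kinetics
#'
#' @param object A `diffusion_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diffusion_fit
#' @export
autoplot.diffusion_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$yield_mg_per_g)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$yield_fitted),
                       colour = "steelblue", na.rm = TRUE) +
    ggplot2::labs(x = "Time (min)", y = "Yield (mg/g)",
                  title = sprintf("Diffusion fit: De = %.3g m²/s",
                                  object$de)) +
    ggplot2::theme_minimal()
}

#' Plot intraparticle concentration profiles over time
#'
#' One curve per snapshot time; the profile flattens as extraction
#' proceeds and the particle interior depletes towards the surface value.
#'
#' @param object A `diffusion_solution` from [solve_diffusion()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diffusion_solution
#' @export
autoplot.diffusion_solution <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$x_rel, y = .data$c_solid,
                               colour = factor(.data$time_min),
                               group = .data$time_min)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Relative radial position x/r",
                  y = expression(C[s]~(kg/m^3)),
                  colour = "Time (min)",
                  title = "Intraparticle phenolic distribution") +
    ggplot2::theme_minimal()
}

#' Plot a fitted De(AED, T) response surface
#'
#' Filled-contour rendering of the quadratic surface over the calibration
#' box, with the fitted design points overlaid.
#'
#' @param object A `de_surface_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot de_surface_fit
#' @export
autoplot.de_surface_fit <- function(object, ...) {
  rng_a <- range(object$data$aed_w_per_l)
  rng_t <- range(object$data$temp_c)
  grid <- tidyr::expand_grid(
    aed_w_per_l = seq(rng_a[1], rng_a[2], length.out = 60),
    temp_c = seq(rng_t[1], rng_t[2], length.out = 60)
  )
  grid$de <- eval_de_surface(grid$aed_w_per_l, grid$temp_c,
                             object$coefficients)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$aed_w_per_l,
                                     y = .data$temp_c)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$de * 1e10)) +
    ggplot2::geom_point(data = object$data, colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "AED (W/L)", y = "Temperature (°C)",
                  fill = expression(D[e]%*%10^10~(m^2/s)),
                  title = "Effective-diffusivity response surface") +
    ggplot2::theme_minimal()
}

#' Parity plot for a trained network surrogate
#'
#' Observed versus predicted yields, coloured by train/validation/test
#' split, with the 1:1 line.
#'
#' @param object An `ann_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ann_fit
#' @export
autoplot.ann_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$yield_mg_per_g,
                               y = .data$yield_pred,
                               colour = .data$split)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Observed yield (mg/g)", y = "Predicted yield (mg/g)",
                  colour = "Split",
                  title = "Network surrogate parity") +
    ggplot2::theme_minimal()
}

#' Plot a factorial kinetics dataset
#'
#' Yield-versus-time curves faceted by temperature and coloured by acoustic
#' energy density.
#'
#' @param data A kinetics tibble with columns `time_min`, `yield_mg_per_g`,
#'   `aed_w_per_l`, `temp_c`.
#' @return A ggplot object.
#' @export
plot_kinetics_grid <- function(data) {
  ggplot2::ggplot(tibble::as_tibble(data),
                  ggplot2::aes(x = .data$time_min, y = .data$yield_mg_per_g,
                               colour = factor(.data$aed_w_per_l),
                               group = .data$aed_w_per_l)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$temp_c),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time (min)", y = "Yield (mg/g)",
                  colour = "AED (W/L)") +
    ggplot2::theme_minimal()
}
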