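#' Tidy a binodal curve fit
#'
#' @param x A `binodal_fit` from [fit_binodal()].
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per coefficient (`term`,
#'   `estimate`); `glance()`: a one-row fit summary; `augment()`: the fitted
#'   points with `.fitted` and `.resid`.
#' @method tidy binodal_fit
#' @export
tidy.binodal_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c", "d"),
                 estimate = as.numeric(unlist(x$coefficients)))
}

#' @rdname tidy.binodal_fit
#' @method glance binodal_fit
#' @export
glance.binodal_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, aad_percent = x$aad_percent,
                 rmse = x$rmse, n_points = x$n_points, method = x$method)
}

#' @rdname tidy.binodal_fit
#' @method augment binodal_fit
#' @export
augment.binodal_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted, .resid = x$residuals)
}

#' Tidy an effective-diffusivity fit
#'
#' @param x A `diffusion_fit` from [fit_de()].
#' @param ... Unused.
#' @return `tidy()`: one row with the estimated De; `glance()`: a one-row
#'   fit summary; `augment()`: the kinetics data with fitted yields.
#' @method tidy diffusion_fit
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(term = "de_m2_per_s", estimate = x$de)
}

#' @rdname tidy.diffusion_fit
#' @method glance diffusion_fit
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(de_m2_per_s = x$de, r_squared = x$r_squared, rmse = x$rmse,
                 aad_percent = x$aad_percent, n_radial = x$n_radial,
                 at_bound = x$at_bound)
}

#' @rdname tidy.diffusion_fit
#' @method augment diffusion_fit
#' @export
augment.diffusion_fit <- function(x, ...) {
  x$data
}

#' Tidy a De response-surface fit
#'
#' @param x A `de_surface_fit` from [fit_de_surface()].
#' @param ... Unused.
#' @return `tidy()`: one row per polynomial term; `glance()`: a one-row fit
#'   summary; `augment()`: the De table with fitted values.
#' @method tidy de_surface_fit
#' @export
tidy.de_surface_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = as.numeric(unlist(x$coefficients)))
}

#' @rdname tidy.de_surface_fit
#' @method glance de_surface_fit
#' @export
glance.de_surface_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, rmse = x$rmse,
                 aad_percent = x$aad_percent, n = x$n)
}

#' @rdname tidy.de_surface_fit
#' @method augment de_surface_fit
#' @export
augment.de_surface_fit <- function(x, ...) {
  x$data
}

#' Tidy a trained network surrogate
#'
#' @param x An `ann_fit` from [ann_train()].
#' @param ... Unused.
#' @return `tidy()`: per-split goodness-of-fit metrics; `glance()`: the
#'   overall one-row summary; `augment()`: the training data with split
#'   labels and predictions.
#' @method tidy ann_fit
#' @export
tidy.ann_fit <- function(x, ...) {
  x$metrics
}

#' @rdname tidy.ann_fit
#' @method glance ann_fit
#' @export
glance.ann_fit <- function(x, ...) {
  ov <- x$metrics[x$metrics$split == "overall",
                  c("r_squared", "rmse", "aad_percent", "n")]
  dplyr::mutate(ov, n_hidden = x$n_hidden, seed = x$seed)
}

#' @rdname tidy.ann_fit
#' @method augment ann_fit
#' @export
augment.ann_fit <- function(x, ...) {
  x$data
}
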