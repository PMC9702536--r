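#' Quadratic response surface of the effective diffusivity
#'
#' The effective diffusion coefficient of phenolics increases with both the
#' acoustic energy density (AED) delivered by the ultrasound probe and the
#' extraction temperature. Over the experimental box AED in [41.1, 111.2]
#' W/L and T in [20, 40] degC, De is well described by a full quadratic
#' polynomial in scaled units:
#' \deqn{D_e \times 10^{10} = \beta_0 + \beta_1 AED + \beta_2 T +
#'       \beta_3 AED^2 + \beta_4 T^2 + \beta_5\, AED \cdot T}
#' with \eqn{D_e} in m^2/s.
#'
#' `de_surface_coefficients()` bundles an arbitrary coefficient set;
#' `reference_de_surface()` returns the fitted constants reported for this
#' extraction system: \eqn{(-1.599,\ 0.02055,\ 0.1213,\ -6.285\times10^{-5},
#' \ -6.25\times10^{-5},\ -7.966\times10^{-5})}.
#'
#' @param intercept,aed,temp,aed2,temp2,aed_temp The six polynomial
#'   coefficients (for De x 1e10 in m^2/s, AED in W/L, T in degC).
#' @return A named list of class `de_surface_coefficients`.
#' @export
de_surface_coefficients <- function(intercept, aed, temp, aed2, temp2,
                                    aed_temp) {
  vals <- c(intercept = intercept, aed = aed, temp = temp,
            aed2 = aed2, temp2 = temp2, aed_temp = aed_temp)
  if (length(vals) != 6L || !all(is.finite(vals))) {
    abort("All six surface coefficients must be finite scalars.",
          class = "uatpe_domain_error")
  }
  structure(as.list(vals), class = "de_surface_coefficients")
}

#' @rdname de_surface_coefficients
#' @export
reference_de_surface <- function() {
  de_surface_coefficients(intercept = -1.599, aed = 0.02055, temp = 0.1213,
                          aed2 = -6.285e-5, temp2 = -6.25e-5,
                          aed_temp = -7.966e-5)
}

as_de_surface_coefficients <- function(x) {
  if (inherits(x, "de_surface_coefficients")) return(x)
  if (inherits(x, "de_surface_fit")) return(x$coefficients)
  if (is.numeric(x) && length(x) == 6L) {
    return(de_surface_coefficients(x[[1]], x[[2]], x[[3]], x[[4]], x[[5]],
                                   x[[6]]))
  }
  nm <- c("intercept", "aed", "temp", "aed2", "temp2", "aed_temp")
  if (is.list(x) && all(nm %in% names(x))) {
    return(do.call(de_surface_coefficients, x[nm]))
  }
  abort("Cannot interpret `coeffs` as De-surface coefficients.",
        class = "uatpe_domain_error")
}

#' @export
print.de_surface_coefficients <- function(x, ...) {
  cat("Quadratic De(AED, T) surface coefficients (De x 1e10, m^2/s):\n")
  print(unlist(x))
  invisible(x)
}

#' Evaluate the De(AED, T) surface
#'
#' @param aed Acoustic energy density (W/L). Values outside the calibration
#'   range [41.1, 111.2] W/L trigger a warning (extrapolation).
#' @param temperature Temperature (degC); calibration range [20, 40] degC.
#' @param coeffs A [de_surface_coefficients] object (or `de_surface_fit`).
#' @return Effective diffusivity De in m^2/s (the polynomial value times
#'   1e-10), vectorised over `aed`/`temperature`.
#' @examples
#' eval_de_surface(96.1, 30, reference_de_surface())  # ~3.15e-10 m^2/s
#' @export
eval_de_surface <- function(aed, temperature, coeffs) {
  coeffs <- as_de_surface_coefficients(coeffs)
  if (any(!is.finite(c(aed, temperature)))) {
    abort("`aed` and `temperature` must be finite.",
          class = "uatpe_domain_error")
  }
  if (any(aed < 41.1 | aed > 111.2)) {
    warn("AED outside the calibration range [41.1, 111.2] W/L; extrapolating.")
  }
  if (any(temperature < 20 | temperature > 40)) {
    warn("Temperature outside the calibration range [20, 40] degC; extrapolating.")
  }
  1e-10 * (coeffs$intercept + coeffs$aed * aed + coeffs$temp * temperature +
             coeffs$aed2 * aed^2 + coeffs$temp2 * temperature^2 +
             coeffs$aed_temp * aed * temperature)
}

#' Fit the quadratic De(AED, T) surface by ordinary least squares
#'
#' @param data A data frame with columns `aed_w_per_l`, `temp_c`,
#'   `de_m2_per_s`; at least 6 rows spanning at least 2 AED and 2
#'   temperature levels.
#' @return An object of class `de_surface_fit`: list with `coefficients`
#'   ([de_surface_coefficients]), `r_squared`, `rmse` (on De x 1e10),
#'   `aad_percent`, `data` (with `de_fitted`), `n`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' grid <- tidyr::expand_grid(aed_w_per_l = c(41.1, 63.5, 96.1, 111.2),
#'                            temp_c = c(20, 30, 40))
#' grid$de_m2_per_s <- eval_de_surface(grid$aed_w_per_l, grid$temp_c,
#'                                     reference_de_surface())
#' fit_de_surface(grid)
#' @export
fit_de_surface <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("aed_w_per_l", "temp_c", "de_m2_per_s")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "uatpe_schema_error")
  }
  if (nrow(data) < 6L) {
    abort("At least 6 rows are needed for the 6-term quadratic surface.",
          class = "uatpe_insufficient_data_error")
  }
  if (length(unique(data$aed_w_per_l)) < 2L ||
      length(unique(data$temp_c)) < 2L) {
    abort("Design is rank-deficient: need >= 2 AED and >= 2 temperature levels.",
          class = "uatpe_singular_design_error")
  }

  df <- dplyr::mutate(data, de10 = .data$de_m2_per_s * 1e10)
  fit <- lm(de10 ~ aed_w_per_l + temp_c + I(aed_w_per_l^2) + I(temp_c^2) +
              I(aed_w_per_l * temp_c), data = df)
  if (anyNA(coef(fit))) {
    abort("Design is rank-deficient for the full quadratic basis.",
          class = "uatpe_singular_design_error")
  }
  co <- de_surface_coefficients(
    intercept = coef(fit)[[1]], aed = coef(fit)[[2]], temp = coef(fit)[[3]],
    aed2 = coef(fit)[[4]], temp2 = coef(fit)[[5]], aed_temp = coef(fit)[[6]]
  )
  fitted10 <- as.numeric(predict(fit))
  m <- fit_metrics(df$de10, fitted10)
  structure(
    list(coefficients = co, r_squared = m$r_squared, rmse = m$rmse,
         aad_percent = m$aad_percent,
         data = dplyr::mutate(data, de_fitted = fitted10 * 1e-10),
         n = nrow(data)),
    class = "de_surface_fit"
  )
}

#' @export
print.de_surface_fit <- function(x, ...) {
  cat("Quadratic De(AED, T) surface fit, n =", x$n, "\n")
  print(unlist(x$coefficients))
  cat(sprintf("R^2 = %.5f\n", x$r_squared))
  invisible(x)
}
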