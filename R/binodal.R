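#' Reference binodal coefficients for the ethanol-ammonium-sulfate system
#'
#' Constructor and reference values for the four constants of the empirical
#' alcohol-salt binodal relation
#' \deqn{w_1 = \exp(a + b\sqrt{w_2} + c w_2 + d w_2^2)}
#' where \eqn{w_1} is the ethanol mass fraction and \eqn{w_2} the ammonium
#' sulfate mass fraction, both on \eqn{[0, 1]}.
#'
#' `binodal_coefficients()` validates and bundles an arbitrary coefficient
#' set; `reference_binodal_coefficients()` returns the fitted constants
#' reported for the ethanol-ammonium-sulfate system studied here,
#' \eqn{(a, b, c, d) = (-0.1408, -2.882, -0.3998, -5.608)}.
#'
#' @param a,b,c,d Finite real fitting constants (dimensionless).
#' @return A named list of class `binodal_coefficients`.
#' @examples
#' co <- reference_binodal_coefficients()
#' eval_binodal(0.20, co)
#' @export
binodal_coefficients <- function(a, b, c, d) {
  vals <- c(a = a, b = b, c = c, d = d)
  if (length(vals) != 4L || !all(is.finite(vals))) {
    abort("Binodal coefficients a, b, c, d must all be finite scalars.",
          class = "uatpe_domain_error")
  }
  structure(as.list(vals), class = "binodal_coefficients")
}

#' @rdname binodal_coefficients
#' @export
reference_binodal_coefficients <- function() {
  binodal_coefficients(a = -0.1408, b = -2.882, c = -0.3998, d = -5.608)
}

as_binodal_coefficients <- function(x) {
  if (inherits(x, "binodal_coefficients")) return(x)
  if (inherits(x, "binodal_fit")) return(x$coefficients)
  if (is.numeric(x) && length(x) == 4L) {
    return(binodal_coefficients(x[[1]], x[[2]], x[[3]], x[[4]]))
  }
  if (is.list(x) && all(c("a", "b", "c", "d") %in% names(x))) {
    return(binodal_coefficients(x$a, x$b, x$c, x$d))
  }
  abort("Cannot interpret `coeffs` as binodal coefficients.",
        class = "uatpe_domain_error")
}

#' @export
print.binodal_coefficients <- function(x, ...) {
  cat("Binodal coefficients (w1 = exp(a + b*sqrt(w2) + c*w2 + d*w2^2)):\n")
  print(unlist(x))
  invisible(x)
}

#' Evaluate the binodal curve
#'
#' Returns the alcohol (ethanol) mass fraction on the binodal curve at the
#' given salt mass fraction(s), \eqn{w_1 = \exp(a + b\sqrt{w_2} + c w_2 +
#' d w_2^2)}. The result is strictly positive by construction.
#'
#' @param w2 Numeric vector of salt mass fractions in \eqn{[0, 1]}.
#' @param coeffs A [binodal_coefficients] object (or a `binodal_fit`, whose
#'   coefficients are used).
#' @return Numeric vector of alcohol mass fractions, same length as `w2`.
#' @examples
#' eval_binodal(c(0, 0.2), reference_binodal_coefficients())
#' @export
eval_binodal <- function(w2, coeffs) {
  coeffs <- as_binodal_coefficients(coeffs)
  if (!is.numeric(w2) || any(!is.finite(w2)) || any(w2 < 0) || any(w2 > 1)) {
    abort("`w2` must be a salt mass fraction in [0, 1].",
          class = "uatpe_domain_error")
  }
  exp(coeffs$a + coeffs$b * sqrt(w2) + coeffs$c * w2 + coeffs$d * w2^2)
}

validate_binodal_points <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("w2", "w1") %in% names(data))) {
    abort("Binodal data must have columns `w2` and `w1` (mass fractions).",
          class = "uatpe_schema_error")
  }
  if (!all(is.finite(data$w1)) || !all(is.finite(data$w2))) {
    abort("Binodal compositions must be finite.", class = "uatpe_domain_error")
  }
  if (any(data$w1 < 0) || any(data$w2 < 0) || any(data$w1 + data$w2 > 1)) {
    abort("Mass fractions must satisfy w1 >= 0, w2 >= 0, w1 + w2 <= 1.",
          class = "uatpe_domain_error")
  }
  data
}

#' Fit the empirical binodal curve to composition data
#'
#' Estimates the four constants of the alcohol-salt binodal relation by least
#' squares. Two fitting spaces are offered. `method = "log-linear"` solves
#' the exact linear least-squares problem in \eqn{\ln w_1} (the model is
#' linear in the coefficients after the log transform). `method =
#' "nonlinear"` (default) minimises squared error in \eqn{w_1} itself by
#' Levenberg-Marquardt, initialised from the log-linear solution; this
#' matches the convention under which the fit quality metrics
#' (\eqn{R^2}, AAD) are reported on \eqn{w_1}. On noiseless data the two
#' methods agree to numerical precision.
#'
#' @param data A data frame with columns `w2` (salt mass fraction) and `w1`
#'   (alcohol mass fraction), at least 5 rows, all `w1 > 0`.
#' @param method `"nonlinear"` (default) or `"log-linear"`.
#' @return An object of class `binodal_fit`: a list with elements
#'   `coefficients` ([binodal_coefficients]), `r_squared`, `aad_percent`,
#'   `residuals` (signed deviations in `w1`, observed minus fitted),
#'   `fitted`, `data`, `n_points`, `method`. Supports [tidy()], [glance()],
#'   [augment()] and [autoplot()].
#' @examples
#' pts <- tibble::tibble(w2 = seq(0.02, 0.35, length.out = 20))
#' pts$w1 <- eval_binodal(pts$w2, reference_binodal_coefficients())
#' fit <- fit_binodal(pts)
#' glance(fit)
#' @export
fit_binodal <- function(data, method = c("nonlinear", "log-linear")) {
  method <- match.arg(method)
  data <- validate_binodal_points(data)
  if (nrow(data) < 5L) {
    abort("At least 5 binodal points are required to fit 4 coefficients.",
          class = "uatpe_insufficient_data_error")
  }
  if (any(data$w1 <= 0)) {
    abort("All `w1` must be strictly positive (log transform must exist).",
          class = "uatpe_domain_error")
  }
  if (length(unique(data$w2)) < 4L) {
    abort("`w2` values span too few distinct levels for a 4-parameter fit.",
          class = "uatpe_insufficient_data_error")
  }

  # exact linear LS in ln(w1); also the nonlinear initialisation
  ll <- lm(log(w1) ~ sqrt(w2) + w2 + I(w2^2), data = data)
  start <- setNames(as.numeric(coef(ll)), c("a", "b", "c", "d"))

  if (method == "nonlinear") {
    nl <- tryCatch(
      minpack.lm::nlsLM(
        w1 ~ exp(a + b * sqrt(w2) + c * w2 + d * w2^2),
        data = data, start = as.list(start),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) {
        abort(
          paste0("Nonlinear binodal fit failed to converge (",
                 conditionMessage(e),
                 "); the log-linear solution is attached as `fallback`."),
          class = "uatpe_convergence_error",
          fallback = start
        )
      }
    )
    est <- coef(nl)
  } else {
    est <- start
  }

  co <- binodal_coefficients(est[["a"]], est[["b"]], est[["c"]], est[["d"]])
  fitted_w1 <- eval_binodal(data$w2, co)
  m <- fit_metrics(data$w1, fitted_w1)

  structure(
    list(
      coefficients = co,
      r_squared = m$r_squared,
      aad_percent = m$aad_percent,
      rmse = m$rmse,
      residuals = data$w1 - fitted_w1,
      fitted = fitted_w1,
      data = data,
      n_points = nrow(data),
      method = method
    ),
    class = "binodal_fit"
  )
}

#' @export
print.binodal_fit <- function(x, ...) {
  cat("Binodal curve fit (", x$method, "), ", x$n_points, " points\n", sep = "")
  print(unlist(x$coefficients))
  cat(sprintf("R^2 = %.6f, AAD = %.3f%%\n", x$r_squared, x$aad_percent))
  invisible(x)
}

#' Classify compositions into one-phase and two-phase regions
#'
#' A composition separates into two aqueous phases when it lies on or above
#' the binodal curve: `two-phase` iff \eqn{w_1 \ge} [eval_binodal]\eqn{(w_2)}.
#' Points exactly on the curve are classified `two-phase` (the separating
#' boundary belongs to the two-phase region for screening purposes).
#'
#' @param data A data frame with columns `w2` and `w1` (mass fractions).
#' @param coeffs Binodal coefficients (or a `binodal_fit`).
#' @return The input as a tibble with added columns `w1_binodal` (curve value
#'   at each `w2`) and `region` (factor, `"one-phase"`/`"two-phase"`).
#' @examples
#' classify_region(tibble::tibble(w2 = 0.20, w1 = 0.30),
#'                 reference_binodal_coefficients())
#' @export
classify_region <- function(data, coeffs) {
  data <- validate_binodal_points(data)
  curve <- eval_binodal(data$w2, coeffs)
  dplyr::mutate(
    data,
    w1_binodal = curve,
    region = factor(ifelse(.data$w1 >= curve, "two-phase", "one-phase"),
                    levels = c("one-phase", "two-phase"))
  )
}
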