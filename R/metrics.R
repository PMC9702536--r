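#' Goodness-of-fit metrics shared by every fitting stage
#'
#' Computes the three statistics used throughout the package to judge model
#' fits: the coefficient of determination \eqn{R^2 = 1 - SSE/SST}, the root
#' mean square error \eqn{RMSE = \sqrt{SSE/n}} (no degrees-of-freedom
#' correction; `n` is the full vector length), and the average absolute
#' relative deviation \eqn{AAD = 100 \cdot \mathrm{mean}(|pred - obs| / obs)}
#' expressed in percent.
#'
#' Two degenerate cases are flagged rather than failing: if the observed
#' values have zero variance \eqn{R^2} is undefined and returned as `NA`
#' (with `r_squared_defined = FALSE`); if any observed value is exactly zero
#' the AAD is undefined and returned as `NA` (with `aad_defined = FALSE`).
#' RMSE is always returned.
#'
#' @param observed Numeric vector of observed (experimental) values.
#' @param predicted Numeric vector of model predictions, same length.
#'
#' @return A one-row tibble with columns `r_squared`, `rmse`, `aad_percent`,
#'   `n`, `r_squared_defined`, `aad_defined`.
#'
#' @examples
#' fit_metrics(c(1, 2, 3), c(1, 2, 3))     # perfect fit: R2 = 1, RMSE = 0
#' fit_metrics(c(2, 4), c(3, 3))           # R2 = 0, RMSE = 1, AAD = 37.5
#' @export
fit_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have the same length.",
          class = "uatpe_shape_error")
  }
  if (length(observed) == 0L) {
    abort("`observed` must be non-empty.", class = "uatpe_shape_error")
  }
  if (!all(is.finite(observed)) || !all(is.finite(predicted))) {
    abort("All observed and predicted values must be finite.",
          class = "uatpe_domain_error")
  }
  n <- length(observed)
  resid <- predicted - observed
  sse <- sum(resid^2)
  sst <- sum((observed - mean(observed))^2)

  r2_ok <- sst > 0
  aad_ok <- all(observed != 0)

  tibble::tibble(
    r_squared = if (r2_ok) 1 - sse / sst else NA_real_,
    rmse = sqrt(sse / n),
    aad_percent = if (aad_ok) 100 * mean(abs(resid) / abs(observed)) else NA_real_,
    n = n,
    r_squared_defined = r2_ok,
    aad_defined = aad_ok
  )
}
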