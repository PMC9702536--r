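#' Partition coefficient between the two aqueous phases
#'
#' The partition coefficient \eqn{K = C_T / C_B} is the ratio of solute
#' concentration in the top (alcohol-rich) phase to the bottom (salt-rich)
#' phase. \eqn{K > 1} means the solute favours the top phase, as phenolics
#' do in the ethanol-ammonium-sulfate system; sugars partition to the bottom
#' phase with smaller \eqn{K}.
#'
#' @param c_top Concentration in the top phase (mg/L, >= 0).
#' @param c_bottom Concentration in the bottom phase (mg/L, > 0). A zero
#'   bottom-phase concentration means all-top-phase partitioning with
#'   unbounded K and raises a domain error rather than returning infinity.
#' @return Numeric vector of dimensionless partition coefficients.
#' @examples
#' partition_coefficient(24.46, 2.0)  # 12.23
#' @export
partition_coefficient <- function(c_top, c_bottom) {
  check_conc <- function(x, nm) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
      abort(paste0("`", nm, "` must be finite and non-negative."),
            class = "uatpe_domain_error")
    }
  }
  check_conc(c_top, "c_top")
  check_conc(c_bottom, "c_bottom")
  if (any(c_bottom == 0)) {
    abort("`c_bottom` is zero: the partition coefficient is unbounded (all-top-phase partitioning).",
          class = "uatpe_domain_error")
  }
  c_top / c_bottom
}

#' Phase recoveries from concentrations and volumes
#'
#' Recovery is the percentage of total solute mass residing in each phase,
#' weighting concentrations by phase volumes:
#' \deqn{Y_T = 100 \frac{C_T V_T}{C_T V_T + C_B V_B}, \qquad
#'       Y_B = 100 \frac{C_B V_B}{C_T V_T + C_B V_B}.}
#' \eqn{Y_T + Y_B = 100} exactly for every valid input. Equivalently
#' \eqn{Y_T = 100\, K R / (K R + 1)} with \eqn{R = V_T / V_B}.
#'
#' @param c_top,c_bottom Phase concentrations (mg/L, >= 0).
#' @param v_top,v_bottom Phase volumes (L, > 0).
#' @return A tibble with columns `y_top`, `y_bottom` (percent).
#' @examples
#' recoveries(12.23, 1.0, 1.216, 1.0)  # top-phase recovery ~93.70%
#' @export
recoveries <- function(c_top, c_bottom, v_top, v_bottom) {
  if (any(!is.finite(c(c_top, c_bottom, v_top, v_bottom)))) {
    abort("All concentrations and volumes must be finite.",
          class = "uatpe_domain_error")
  }
  if (any(c_top < 0) || any(c_bottom < 0)) {
    abort("Concentrations must be non-negative.", class = "uatpe_domain_error")
  }
  if (any(v_top <= 0) || any(v_bottom <= 0)) {
    abort("Phase volumes must be strictly positive.",
          class = "uatpe_domain_error")
  }
  m_top <- c_top * v_top
  m_bottom <- c_bottom * v_bottom
  total <- m_top + m_bottom
  if (any(total == 0)) {
    abort("Zero total solute mass: recoveries are undefined.",
          class = "uatpe_domain_error")
  }
  y_top <- 100 * m_top / total
  tibble::tibble(y_top = y_top, y_bottom = 100 - y_top)
}

#' Partition statistics for a table of phase samples
#'
#' Tidy wrapper computing, per row of a phase-sample table, the partition
#' coefficient and top/bottom recoveries.
#'
#' @param data A data frame with columns `c_top`, `c_bottom` (mg/L),
#'   `v_top`, `v_bottom` (L); any further columns (e.g. `analyte`) are
#'   carried through.
#' @return The input as a tibble with added columns `k`, `y_top`, `y_bottom`.
#' @examples
#' partition_stats(tibble::tibble(analyte = "phenolics",
#'                                c_top = 24.46, c_bottom = 2,
#'                                v_top = 1.216, v_bottom = 1))
#' @export
partition_stats <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("c_top", "c_bottom", "v_top", "v_bottom")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "uatpe_schema_error")
  }
  rec <- recoveries(data$c_top, data$c_bottom, data$v_top, data$v_bottom)
  dplyr::mutate(data,
                k = partition_coefficient(data$c_top, data$c_bottom),
                y_top = rec$y_top, y_bottom = rec$y_bottom)
}

#' Purity of a phenolic extract
#'
#' Purity is the ratio of total phenolic mass to the mass of the dried
#' extract, in percent.
#'
#' @param phenolic_mass Phenolic mass (mg), `0 <= phenolic_mass <= extract_mass`.
#' @param extract_mass Total dried extract mass (mg, > 0).
#' @return Purity in percent, in \eqn{[0, 100]}.
#' @examples
#' purity_percent(6.98, 100)
#' @export
purity_percent <- function(phenolic_mass, extract_mass) {
  if (any(!is.finite(c(phenolic_mass, extract_mass))) ||
      any(extract_mass <= 0)) {
    abort("`extract_mass` must be finite and strictly positive.",
          class = "uatpe_domain_error")
  }
  if (any(phenolic_mass < 0) || any(phenolic_mass > extract_mass)) {
    abort("`phenolic_mass` must lie in [0, extract_mass].",
          class = "uatpe_domain_error")
  }
  100 * phenolic_mass / extract_mass
}

#' Percent increase of a value over a reference
#'
#' \eqn{100 (x_{new}/x_{ref} - 1)}; used to compare purities and yields
#' across extraction methods (e.g. ultrasound-assisted two-phase extraction
#' versus conventional ethanol extraction).
#'
#' @param new_value New value (same units as `reference_value`).
#' @param reference_value Reference value, strictly positive.
#' @return Percent change (may be negative).
#' @examples
#' percent_increase(6.98, 4.41)  # ~58.3% purity gain over crude extraction
#' @export
percent_increase <- function(new_value, reference_value) {
  if (any(!is.finite(c(new_value, reference_value))) ||
      any(reference_value <= 0)) {
    abort("`reference_value` must be finite and strictly positive.",
          class = "uatpe_domain_error")
  }
  100 * (new_value / reference_value - 1)
}

#' Extraction yield as a fraction of raw-material content
#'
#' For an individual compound (e.g. an anthocyanin monomer), the percentage
#' of the raw material's total content recovered by an extraction:
#' \eqn{100 \cdot extracted / raw}.
#'
#' @param extracted Extracted amount (ug/g dry material, >= 0).
#' @param raw_content Total content in the raw material (ug/g, > 0).
#' @return Percent of total content recovered.
#' @examples
#' yield_fraction(46.47, 61.28)  # ~75.8%
#' @export
yield_fraction <- function(extracted, raw_content) {
  if (any(!is.finite(c(extracted, raw_content))) || any(raw_content <= 0)) {
    abort("`raw_content` must be finite and strictly positive.",
          class = "uatpe_domain_error")
  }
  if (any(extracted < 0)) {
    abort("`extracted` must be non-negative.", class = "uatpe_domain_error")
  }
  100 * extracted / raw_content
}

#' Phase-volume ratio implied by a (K, Y_top) pair
#'
#' Inverts the recovery identity \eqn{Y_T = 100 K R/(K R + 1)} for the
#' top-to-bottom volume ratio \eqn{R = V_T/V_B}: \eqn{R = Y_T / (K (100 -
#' Y_T))}. Useful as a consistency check when a study reports partition
#' coefficients and recoveries but not the phase volumes.
#'
#' @param k Partition coefficient (> 0).
#' @param y_top Top-phase recovery in percent, in (0, 100).
#' @return Implied volume ratio \eqn{V_T/V_B}.
#' @examples
#' implied_volume_ratio(4.80, 79.86)  # sugar partition, ultrasound run
#' @export
implied_volume_ratio <- function(k, y_top) {
  if (any(!is.finite(c(k, y_top))) || any(k <= 0) ||
      any(y_top <= 0) || any(y_top >= 100)) {
    abort("Need k > 0 and y_top strictly inside (0, 100).",
          class = "uatpe_domain_error")
  }
  y_top / (k * (100 - y_top))
}
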