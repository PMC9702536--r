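#' Configuration for the synthetic-data generators
#'
#' Collects the seed, noise model and experimental grids used by
#' [gen_binodal()], [gen_kinetics_grid()] and [gen_partition()]. The default
#' grids are the full-factorial study conditions: four acoustic energy
#' densities (41.1, 63.5, 96.1, 111.2 W/L), three temperatures (20, 30,
#' 40 degC), and nine sampling times between 2.5 and 60 min; binodal points
#' cover salt mass fractions 0.02 to 0.35.
#'
#' Noise, when enabled, is multiplicative Gaussian truncated at zero
#' (positive quantities with roughly proportional assay error):
#' \eqn{y = \max(0, y_{true}(1 + \epsilon))}, \eqn{\epsilon \sim N(0,
#' noise\_rel)}.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, truth), so identical seeds give identical tables.
#' @param noise_model `"none"` or `"multiplicative-gaussian"`.
#' @param noise_rel Relative standard deviation of the noise (>= 0).
#' @param aed_levels Acoustic energy densities (W/L).
#' @param temperatures Temperatures (degC).
#' @param time_points_min Sampling times (min), strictly positive.
#' @param w2_range Salt-mass-fraction range for binodal points, within
#'   (0, 0.5].
#' @param n_binodal Number of binodal points.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         noise_model = c("none", "multiplicative-gaussian"),
                         noise_rel = 0,
                         aed_levels = c(41.1, 63.5, 96.1, 111.2),
                         temperatures = c(20, 30, 40),
                         time_points_min = c(2.5, 5, 10, 15, 20, 30, 40, 50, 60),
                         w2_range = c(0.02, 0.35),
                         n_binodal = 20) {
  noise_model <- match.arg(noise_model)
  if (!is.finite(noise_rel) || noise_rel < 0) {
    abort("`noise_rel` must be >= 0.", class = "uatpe_domain_error")
  }
  if (length(aed_levels) == 0 || length(temperatures) == 0 ||
      length(time_points_min) == 0) {
    abort("Grids must be non-empty.", class = "uatpe_domain_error")
  }
  if (any(time_points_min <= 0)) {
    abort("`time_points_min` must be strictly positive.",
          class = "uatpe_domain_error")
  }
  if (length(w2_range) != 2 || w2_range[1] <= 0 || w2_range[2] > 0.5 ||
      w2_range[1] >= w2_range[2]) {
    abort("`w2_range` must be increasing and within (0, 0.5].",
          class = "uatpe_domain_error")
  }
  structure(
    list(seed = as.integer(seed), noise_model = noise_model,
         noise_rel = noise_rel, aed_levels = aed_levels,
         temperatures = temperatures, time_points_min = time_points_min,
         w2_range = w2_range, n_binodal = as.integer(n_binodal)),
    class = "synth_config"
  )
}

apply_noise <- function(x, cfg) {
  if (cfg$noise_model == "none" || cfg$noise_rel == 0) return(x)
  pmax(0, x * (1 + rnorm(length(x), 0, cfg$noise_rel)))
}

#' Generate synthetic binodal composition points
#'
#' Points are placed on an even salt-fraction grid over `cfg$w2_range`, with
#' alcohol fractions from the truth curve ([eval_binodal()]) perturbed by
#' the configured multiplicative noise.
#'
#' @param cfg A [synth_config()].
#' @param truth Binodal coefficients generating the truth curve; defaults to
#'   [reference_binodal_coefficients()].
#' @return Tibble with columns `w2`, `w1`.
#' @examples
#' gen_binodal(synth_config(seed = 7))
#' @export
gen_binodal <- function(cfg = synth_config(),
                        truth = reference_binodal_coefficients()) {
  stopifnot(inherits(cfg, "synth_config"))
  w2 <- seq(cfg$w2_range[1], cfg$w2_range[2], length.out = cfg$n_binodal)
  w1_true <- eval_binodal(w2, truth)
  withr::with_seed(cfg$seed, {
    tibble::tibble(w2 = w2, w1 = apply_noise(w1_true, cfg))
  })
}

#' Generate a synthetic full-factorial extraction-kinetics dataset
#'
#' For every (AED, temperature) cell of the factorial grid, the effective
#' diffusivity is taken from the response surface ([eval_de_surface()]) and
#' the yield curve is produced by the diffusion forward model
#' ([solve_diffusion()]) at the configured sampling times, then perturbed by
#' the configured noise. This emulates the study design end-to-end, so the
#' inverse fits (per-cell De, De surface, network surrogate) can be tested
#' against a known ground truth.
#'
#' @param cfg A [synth_config()].
#' @param system A [particle_system()].
#' @param surface De-surface coefficients used as the condition-to-De map;
#'   defaults to [reference_de_surface()].
#' @param n_radial Radial shells for the forward solver.
#' @return Tibble with columns `aed_w_per_l`, `temp_c`, `time_min`,
#'   `yield_mg_per_g`, `de_true_m2_per_s` (the generating diffusivity) — a
#'   factorial dataset consumable by [fit_de()] (per cell), [ann_train()],
#'   and, after per-cell De fits, [fit_de_surface()].
#' @examples
#' kin <- gen_kinetics_grid(synth_config(seed = 7))
#' head(kin)
#' @export
gen_kinetics_grid <- function(cfg = synth_config(),
                              system = particle_system(),
                              surface = reference_de_surface(),
                              n_radial = 60) {
  stopifnot(inherits(cfg, "synth_config"))
  grid <- tidyr::expand_grid(aed_w_per_l = cfg$aed_levels,
                             temp_c = cfg$temperatures)
  de <- eval_de_surface(grid$aed_w_per_l, grid$temp_c, surface)
  if (any(de <= 0)) {
    abort("The De surface is non-positive on part of the grid.",
          class = "uatpe_domain_error")
  }
  times_s <- sort(cfg$time_points_min) * 60
  curves <- purrr::pmap_dfr(
    list(grid$aed_w_per_l, grid$temp_c, de),
    function(a, tc, d) {
      kin <- solve_diffusion(system, d, times = times_s,
                             n_radial = n_radial)$kinetics
      tibble::tibble(aed_w_per_l = a, temp_c = tc,
                     time_min = kin$time_min,
                     yield_mg_per_g = kin$yield_mg_per_g,
                     de_true_m2_per_s = d)
    })
  withr::with_seed(cfg$seed, {
    curves$yield_mg_per_g <- apply_noise(curves$yield_mg_per_g, cfg)
  })
  curves
}

#' Generate synthetic phase-partition samples
#'
#' Produces top/bottom concentration-volume records whose partition
#' coefficient equals `k_true` exactly before noise, with total solute
#' concentration `c_total` split between the phases according to `k_true`
#' and volumes in the ratio `volume_ratio` (total volume 1 L).
#'
#' @param cfg A [synth_config()].
#' @param k_true True partition coefficient (> 0).
#' @param volume_ratio Top-to-bottom volume ratio (> 0).
#' @param c_total Total solute mass per unit total volume (mg/L).
#' @param n Number of replicate samples.
#' @return Tibble with columns `c_top`, `c_bottom`, `v_top`, `v_bottom`.
#' @examples
#' gen_partition(synth_config(seed = 7), k_true = 4.80, volume_ratio = 0.826)
#' @export
gen_partition <- function(cfg = synth_config(), k_true, volume_ratio,
                          c_total = 100, n = 3) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.finite(k_true) || k_true <= 0 ||
      !is.finite(volume_ratio) || volume_ratio <= 0) {
    abort("`k_true` and `volume_ratio` must be finite and > 0.",
          class = "uatpe_domain_error")
  }
  v_top <- volume_ratio / (1 + volume_ratio)
  v_bottom <- 1 - v_top
  # split total mass so that c_top / c_bottom = k_true exactly
  c_bottom <- c_total / (k_true * v_top + v_bottom)
  c_top <- k_true * c_bottom
  withr::with_seed(cfg$seed, {
    tibble::tibble(
      c_top = apply_noise(rep(c_top, n), cfg),
      c_bottom = apply_noise(rep(c_bottom, n), cfg),
      v_top = rep(v_top, n),
      v_bottom = rep(v_bottom, n)
    )
  })
}
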