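test_that("generator configuration validates its grids and noise", {
  expect_error(synth_config(noise_rel = -0.1), class = "uatpe_domain_error")
  expect_error(synth_config(w2_range = c(0.4, 0.2)),
               class = "uatpe_domain_error")
  expect_error(synth_config(w2_range = c(0, 0.3)),
               class = "uatpe_domain_error")
  expect_error(synth_config(time_points_min = c(0, 5)),
               class = "uatpe_domain_error")
  expect_error(synth_config(aed_levels = numeric(0)),
               class = "uatpe_domain_error")
})

test_that("noiseless binodal generation lies on the truth curve and round-trips", {
  cfg <- synth_config(seed = 3)
  pts <- gen_binodal(cfg)
  expect_equal(pts$w1,
               eval_binodal(pts$w2, reference_binodal_coefficients()),
               tolerance = 1e-14)
  fit <- fit_binodal(pts)
  expect_equal(unlist(fit$coefficients),
               unlist(reference_binodal_coefficients()), tolerance = 1e-5)
})

test_that("generators are pure functions of the seed", {
  cfg <- synth_config(seed = 9, noise_model = "multiplicative-gaussian",
                      noise_rel = 0.02)
  expect_identical(gen_binodal(cfg), gen_binodal(cfg))
  expect_identical(gen_partition(cfg, 4.8, 0.826),
                   gen_partition(cfg, 4.8, 0.826))
  cfg_small <- synth_config(seed = 9,
                            noise_model = "multiplicative-gaussian",
                            noise_rel = 0.02,
                            aed_levels = c(41.1, 96.1),
                            temperatures = c(20, 40),
                            time_points_min = c(5, 20, 60))
  expect_identical(gen_kinetics_grid(cfg_small), gen_kinetics_grid(cfg_small))
  # different seeds give different noise
  cfg2 <- synth_config(seed = 10, noise_model = "multiplicative-gaussian",
                       noise_rel = 0.02)
  expect_false(identical(gen_binodal(cfg), gen_binodal(cfg2)))
})

test_that("factorial kinetics inherit the De surface and increase with AED", {
  cfg <- synth_config(seed = 7, time_points_min = c(5, 15, 30, 60))
  kin <- gen_kinetics_grid(cfg)
  expect_equal(nrow(kin), 4 * 3 * 4)
  expect_equal(
    unique(kin[, c("aed_w_per_l", "temp_c", "de_true_m2_per_s")])$de_true_m2_per_s,
    eval_de_surface(tidyr::expand_grid(a = cfg$aed_levels,
                                       t = cfg$temperatures)$a,
                    tidyr::expand_grid(a = cfg$aed_levels,
                                       t = cfg$temperatures)$t,
                    reference_de_surface())
  )
  # noiseless yields increase with AED at fixed temperature and time
  wide <- kin |>
    dplyr::arrange(.data$aed_w_per_l) |>
    dplyr::group_by(.data$temp_c, .data$time_min) |>
    dplyr::summarise(mono = all(diff(.data$yield_mg_per_g) > 0),
                     .groups = "drop")
  expect_true(all(wide$mono))
})

test_that("per-cell De fits on the noiseless grid recover the surface map", {
  cfg <- synth_config(seed = 7, aed_levels = c(41.1, 111.2),
                      temperatures = c(20, 40),
                      time_points_min = c(5, 15, 30, 60))
  sys <- particle_system()
  kin <- gen_kinetics_grid(cfg, sys)
  fits <- kin |>
    dplyr::group_by(.data$aed_w_per_l, .data$temp_c) |>
    dplyr::group_modify(function(d, key) {
      tibble::tibble(de_hat = fit_de(d, sys)$de,
                     de_true = d$de_true_m2_per_s[1])
    }) |>
    dplyr::ungroup()
  expect_true(all(abs(fits$de_hat / fits$de_true - 1) < 0.01))
  # and every recovered value sits in the experimentally reported decade
  expect_true(all(fits$de_hat > 1e-10 & fits$de_hat < 1e-9))
})

test_that("partition generation hits the requested K and published recovery pairs", {
  cfg <- synth_config(seed = 3)
  s <- gen_partition(cfg, k_true = 1, volume_ratio = 1)
  st <- partition_stats(s)
  expect_equal(st$k, rep(1, 3), tolerance = 1e-12)
  expect_equal(st$y_top, rep(50, 3), tolerance = 1e-12)

  sugar <- partition_stats(gen_partition(cfg, k_true = 4.80,
                                         volume_ratio = 0.826))
  expect_equal(sugar$y_top, rep(79.86, 3), tolerance = 1e-3)
  expect_error(gen_partition(cfg, k_true = -1, volume_ratio = 1),
               class = "uatpe_domain_error")
})

test_that("noise is multiplicative, zero-truncated and seed-stable in spread", {
  cfg <- synth_config(seed = 8, noise_model = "multiplicative-gaussian",
                      noise_rel = 0.05, n_binodal = 200)
  pts <- gen_binodal(cfg)
  truth <- eval_binodal(pts$w2, reference_binodal_coefficients())
  rel <- pts$w1 / truth - 1
  expect_true(all(pts$w1 >= 0))
  expect_lt(abs(sd(rel) - 0.05), 0.015)
  expect_lt(abs(mean(rel)), 0.02)
})
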