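test_that("particle system derives ensemble geometry and validates inputs", {
  sys <- particle_system()
  expect_equal(sys$v_particles, sys$m_solid / sys$rho_particle)
  expect_equal(sys$area, 3 * sys$v_particles / sys$r)
  expect_equal(sys$n_particles * (4 / 3) * pi * sys$r^3, sys$v_particles,
               tolerance = 1e-12)
  # default bath-to-particle capacity ratio is 20
  expect_equal(sys$v_solution / (sys$k_interface * sys$v_particles), 20)
  expect_error(particle_system(r = 0), class = "uatpe_domain_error")
  expect_error(particle_system(v_solution = 1e-8),
               class = "uatpe_domain_error")
})

test_that("the series solution behaves at its limits and matches the infinite-bath form", {
  expect_equal(crank_fraction(20, 0), 0)
  expect_equal(crank_fraction(2, 50), 1, tolerance = 1e-9)
  expect_equal(crank_fraction(200, 50), 1, tolerance = 1e-9)
  # alpha -> infinity reduces to the classical infinite-bath series
  for (tau in c(0.05, 0.1, 0.3)) {
    expect_equal(crank_fraction(1e6, tau), infinite_bath_fraction(tau),
                 tolerance = 1e-6)
  }
  expect_equal(crank_fraction(1e6, 0.1), 0.7705, tolerance = 1e-3)
  # monotone non-decreasing in tau
  taus <- seq(0, 2, length.out = 50)
  expect_true(all(diff(crank_fraction(20, taus)) >= 0))
  expect_error(crank_fraction(-1, 0.1), class = "uatpe_domain_error")
  expect_error(crank_fraction(2, 0.1, n_roots = 5),
               class = "uatpe_domain_error")
})

test_that("the solver starts from a clean bath and reaches the closed mass balance", {
  sys <- particle_system()
  de <- 3e-10
  sol <- solve_diffusion(sys, de, times = c(0, 60, 600))
  expect_equal(sol$kinetics$yield_mg_per_g[1], 0)
  # tau >> 5: bath concentration at the closed-system equilibrium
  t_eq <- 6 * sys$r^2 / de
  sol_eq <- solve_diffusion(sys, de, times = t_eq)
  cl_inf <- sys$cs0 * sys$v_particles / (sys$v_solution + sys$v_particles)
  expect_equal(sol_eq$kinetics$c_liquid, cl_inf, tolerance = 1e-5)
  # equilibrium yield is the design value of 18 mg/g
  expect_equal(sol_eq$kinetics$yield_mg_per_g, 18, tolerance = 1e-4)
})

test_that("solver fraction matches the series oracle at a reference grid point", {
  sys <- system_with_alpha(20)
  de <- 3e-10
  tau <- 0.3
  sol <- solve_diffusion(sys, de, times = tau * sys$r^2 / de, n_radial = 120)
  expect_equal(extracted_fraction(sol, 20), crank_fraction(20, tau),
               tolerance = 1e-3)
})

test_that("solution curves are physical: C_L non-decreasing, profile bounded and symmetric-limited", {
  sys <- particle_system()
  sol <- solve_diffusion(sys, 3e-10, times = seq(30, 3600, by = 170))
  expect_true(all(diff(sol$kinetics$c_liquid) > 0))
  expect_true(all(sol$profile$c_solid >= -1e-9))
  expect_true(all(sol$profile$c_solid <= sys$cs0 * (1 + 1e-9)))
  # concavity trend: increments of the yield curve shrink with time
  inc <- diff(sol$kinetics$yield_mg_per_g)
  expect_true(all(diff(inc) < 0))
})

test_that("dimensionless-time identity: scaling De by k and time by 1/k is invariant", {
  sys <- particle_system()
  times <- c(300, 900, 1800, 3600)
  a <- solve_diffusion(sys, 3e-10, times = times)
  b <- solve_diffusion(sys, 3e-9, times = times / 10)
  expect_equal(a$kinetics$yield_mg_per_g, b$kinetics$yield_mg_per_g,
               tolerance = 1e-6)
})

test_that("De is recovered from noiseless and noisy synthetic kinetics", {
  sys <- particle_system()
  de_true <- 3.0e-10
  times <- c(2.5, 5, 10, 15, 20, 30, 40, 50, 60) * 60
  clean <- solve_diffusion(sys, de_true, times = times)$kinetics
  fit <- fit_de(clean, sys)
  expect_lt(abs(fit$de / de_true - 1), 0.01)
  expect_gt(fit$r_squared, 0.999)
  expect_false(fit$at_bound)

  noisy <- clean
  withr::with_seed(42, {
    noisy$yield_mg_per_g <- pmax(0, noisy$yield_mg_per_g *
                                   (1 + rnorm(length(times), 0, 0.03)))
  })
  fit_n <- fit_de(noisy, sys)
  expect_lt(abs(fit_n$de / de_true - 1), 0.10)
})

test_that("De fitting flags degenerate data and bound-constrained optima", {
  sys <- particle_system()
  flat <- tibble::tibble(time_min = c(5, 10, 20), yield_mg_per_g = c(0, 0, 0))
  expect_error(fit_de(flat, sys), class = "uatpe_degenerate_data_error")
  expect_error(fit_de(flat[1:2, ], sys),
               class = "uatpe_insufficient_data_error")
  curve <- solve_diffusion(sys, 3e-10,
                           times = c(5, 15, 30, 60) * 60)$kinetics
  expect_warning(fit_de(curve, sys, bounds = c(1e-12, 1e-11)),
                 "bounds")
})

test_that("diffusion fits expose broom-style methods and a plot", {
  sys <- particle_system()
  curve <- solve_diffusion(sys, 2e-10,
                           times = c(5, 15, 30, 60) * 60)$kinetics
  fit <- fit_de(curve, sys)
  expect_equal(tidy(fit)$estimate, fit$de)
  expect_equal(glance(fit)$n_radial, 60)
  expect_s3_class(autoplot(fit), "ggplot")
  sol <- solve_diffusion(sys, 2e-10, times = c(150, 600, 1800, 3600))
  expect_s3_class(autoplot(sol), "ggplot")
})

test_that("the quadratic De surface evaluates, warns outside calibration, and orders corners", {
  surf <- reference_de_surface()
  expect_equal(eval_de_surface(96.1, 30, surf), 3.1485e-10,
               tolerance = 1e-4)
  expect_equal(eval_de_surface(50, 25, de_surface_coefficients(0, 0, 0, 0, 0, 0)), 0)
  expect_gt(eval_de_surface(111.2, 40, surf), eval_de_surface(41.1, 20, surf))
  expect_warning(eval_de_surface(20, 30, surf), "AED")
  expect_warning(eval_de_surface(96.1, 50, surf), "Temperature")
  # positive over the whole calibration box
  grid <- tidyr::expand_grid(aed = seq(41.1, 111.2, length.out = 15),
                             temp = seq(20, 40, length.out = 15))
  expect_true(all(eval_de_surface(grid$aed, grid$temp, surf) > 0))
})

test_that("surface fitting recovers coefficients exactly from noiseless data and rejects bad designs", {
  grid <- tidyr::expand_grid(aed_w_per_l = c(41.1, 63.5, 96.1, 111.2),
                             temp_c = c(20, 30, 40))
  grid$de_m2_per_s <- eval_de_surface(grid$aed_w_per_l, grid$temp_c,
                                      reference_de_surface())
  fit <- fit_de_surface(grid)
  expect_equal(unlist(fit$coefficients), unlist(reference_de_surface()),
               tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(tidy(fit)$term,
               c("intercept", "aed", "temp", "aed2", "temp2", "aed_temp"))
  expect_s3_class(autoplot(fit), "ggplot")

  one_aed <- grid
  one_aed$aed_w_per_l <- 96.1
  expect_error(fit_de_surface(one_aed), class = "uatpe_singular_design_error")
  expect_error(fit_de_surface(grid[1:4, ]),
               class = "uatpe_insufficient_data_error")

  noisy <- grid
  withr::with_seed(43, {
    noisy$de_m2_per_s <- noisy$de_m2_per_s * (1 + rnorm(12, 0, 0.05))
  })
  expect_gte(fit_de_surface(noisy)$r_squared, 0.9)
})
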