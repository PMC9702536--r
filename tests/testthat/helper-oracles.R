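# Independent reference implementations used as oracles; deliberately naive
# and kept separate from the code paths they check.

# two-pass goodness-of-fit reference
naive_metrics <- function(obs, pred) {
  n <- length(obs)
  sse <- 0
  for (i in seq_len(n)) sse <- sse + (pred[i] - obs[i])^2
  m <- sum(obs) / n
  sst <- 0
  for (i in seq_len(n)) sst <- sst + (obs[i] - m)^2
  aad <- 0
  for (i in seq_len(n)) aad <- aad + abs(pred[i] - obs[i]) / obs[i]
  list(r2 = 1 - sse / sst, rmse = sqrt(sse / n), aad = 100 * aad / n)
}

# classical infinite-bath sphere series, first `n_terms` terms
infinite_bath_fraction <- function(tau, n_terms = 50) {
  n <- seq_len(n_terms)
  1 - (6 / pi^2) * sum(exp(-n^2 * pi^2 * tau) / n^2)
}

# sum of squared w1-errors of a binodal coefficient set
binodal_sse <- function(co, data) {
  pred <- exp(co[1] + co[2] * sqrt(data$w2) + co[3] * data$w2 +
                co[4] * data$w2^2)
  sum((pred - data$w1)^2)
}

# coarse grid search for the best binodal coefficients near a centre point
binodal_grid_oracle <- function(data, centre, spread = 0.10, steps = 5) {
  grids <- lapply(centre, function(v) v * seq(1 - spread, 1 + spread,
                                              length.out = steps))
  best <- Inf
  for (a in grids[[1]]) for (b in grids[[2]]) {
    for (cc in grids[[3]]) for (d in grids[[4]]) {
      s <- binodal_sse(c(a, b, cc, d), data)
      if (s < best) best <- s
    }
  }
  best
}

# reference particle system with a bath-to-particle capacity ratio alpha
system_with_alpha <- function(alpha) {
  base <- particle_system()
  particle_system(v_solution = alpha * base$v_particles)
}

# fraction of ultimately extractable solute released, from a solver run
extracted_fraction <- function(solution, alpha) {
  sys <- solution$system
  m_inf <- sys$cs0 * sys$v_particles * alpha / (alpha + 1)
  solution$kinetics$c_liquid * sys$v_solution / m_inf
}
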