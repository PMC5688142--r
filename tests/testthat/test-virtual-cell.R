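# Virtual-cell simulator: population construction, single-cell dynamics,
# measurement, perturbations, the birth-death oracle and image rendering.

test_that("init_population reproduces the requested heterogeneity", {
  # degenerate distribution: identical cells
  pop0 <- init_population(population_spec(5, cv = 0, seed = 3))
  ebars <- sapply(pop0, function(cl) cl$params$E_bar)
  expect_equal(ebars, rep(cell_params()$E_bar, 5))
  # every cell starts dark-adapted at the no-light steady state
  p <- pop0[[1]]$params
  expect_equal(pop0[[1]]$state$F, p$f0 / p$gamma)
  expect_equal(pop0[[1]]$state$H, 0)

  # determinism under a fixed seed
  a <- init_population(population_spec(20, cv = 0.3, seed = 9))
  b <- init_population(population_spec(20, cv = 0.3, seed = 9))
  expect_identical(a, b)

  # sample CV close to the nominal 0.3 at large n (log-normal moments):
  # se(CV) ~ CV * sqrt((1 + 2 CV^2) / (2 n)) for a log-normal sample
  pop <- init_population(population_spec(1e4, cv = 0.3, seed = 4))
  eb <- sapply(pop, function(cl) cl$params$E_bar)
  cv_hat <- sd(eb) / mean(eb)
  se_cv <- 0.3 * sqrt((1 + 2 * 0.3^2) / (2 * 1e4))
  expect_lt(abs(cv_hat - 0.3), 3 * se_cv)
  expect_lt(abs(mean(eb) - 1), 3 * sd(eb) / sqrt(1e4))

  expect_error(population_spec(0), "positive count")
  expect_error(population_spec(5, cv = -1), "non-negative")
})

test_that("noise-free step_cell follows the closed-form relaxations", {
  p <- cell_params(sigma_E = 0, omega = 0, sigma_m = 0)
  # pure dilution with leak: F(dt) = f0/g + (F0 - f0/g) exp(-g dt)
  st <- cell_state(H = 0, E = p$E_bar, F = 20, length = p$L0)
  out <- step_cell(st, p, u = 0, dt = 6)
  fss <- p$f0 / p$gamma
  expect_equal(out$F, fss + (20 - fss) * exp(-p$gamma * 6), tolerance = 1e-6)
  # activation: H(t) = 1 - exp(-k_H t) under sustained green
  st <- cell_state(H = 0, E = p$E_bar, F = 0, length = p$L0)
  out <- step_cell(st, p, u = 1, dt = 9)
  expect_equal(out$H, 1 - exp(-p$k_H * 9), tolerance = 1e-9)
  # deactivation uses the slower red rate
  out2 <- step_cell(cell_state(H = 1, E = 1, F = 0, length = p$L0),
                    p, u = 0, dt = 9)
  expect_equal(out2$H, exp(-p$k_H_off * 9), tolerance = 1e-9)

  expect_error(step_cell(st, p, u = 2, dt = 6), "0 .red. or 1")
  expect_error(step_cell(st, p, u = 1, dt = -1), "positive")
})

test_that("sub-stepping is converged: halving dt barely moves moments", {
  p <- cell_params()
  set.seed(1); sched <- rbinom(10, 1, 0.5)
  a <- ensemble_moments(p, sched, n_reps = 4000, seed = 5, substep = 0.1)
  b <- ensemble_moments(p, sched, n_reps = 4000, seed = 5, substep = 0.05)
  expect_lt(max(abs(a$mean - b$mean) / pmax(b$mean, 1)), 0.01)
  expect_lt(max(abs(a$var - b$var) / pmax(b$var, 1)), 0.02)
})

test_that("measurement adds truncated Gaussian noise of s.d. sigma_m", {
  p <- cell_params(sigma_m = 0)
  st <- cell_state(F = 7.3, E = 1, length = 2.5)
  expect_identical(measure_cell(st, p), 7.3)
  p1 <- cell_params(sigma_m = 1)
  st0 <- cell_state(F = 0, E = 1, length = 2.5)
  set.seed(2)
  expect_true(all(replicate(50, measure_cell(st0, p1)) >= 0))
  # sample s.d. of repeated measurements matches sigma_m
  set.seed(3)
  ys <- vapply(seq_len(1e5), function(i)
    measure_cell(cell_state(F = 15, E = 1, length = 2.5), p1), numeric(1))
  se_sd <- 1 / sqrt(2 * (1e5 - 1))
  expect_lt(abs(sd(ys) - 1), 3 * se_sd)
  st_dead <- cell_state(F = 1, E = 1, length = 2.5, alive = FALSE)
  expect_error(measure_cell(st_dead, p1), "dead")
})

test_that("perturbation steps growth and ramps responsiveness after delay", {
  p <- cell_params()
  ev <- perturbation_event(t_switch = 600, gamma_factor = 0.7,
                           resp_factor = 1.5, resp_delay = 300,
                           resp_tau = 120, lag = 5)
  expect_identical(apply_perturbation(p, ev, 500), p)    # pre-event identity
  expect_identical(apply_perturbation(p, ev, 604), p)    # still within lag
  far <- apply_perturbation(p, ev, 1e5)
  expect_equal(far$gamma, 0.7 * p$gamma)                 # ~30% slowdown
  expect_equal(far$E_bar, 1.5 * p$E_bar, tolerance = 1e-6)
  # responsiveness still at baseline when the ramp just begins
  at_delay <- apply_perturbation(p, ev, 900)
  expect_equal(at_delay$E_bar, p$E_bar)
  expect_equal(at_delay$gamma, 0.7 * p$gamma)            # growth already shifted
  # idempotent per time query
  expect_identical(apply_perturbation(p, ev, 1000),
                   apply_perturbation(p, ev, 1000))
})

test_that("birth-death oracle matches pure-death and stationary closed forms", {
  # pure death: production off, start at F0
  p <- cell_params(f0 = 0, sigma_E = 0, omega = 0.01)
  F0 <- 10
  so <- ssa_oracle(p, schedule = rep(0, 5), n_reps = 2e4, seed = 6, F0 = F0)
  n0 <- F0 / p$omega
  expmean <- F0 * exp(-p$gamma * so$t)
  expvar <- n0 * exp(-p$gamma * so$t) * (1 - exp(-p$gamma * so$t)) * p$omega^2
  expect_lt(max(abs(so$mean - expmean) / pmax(so$se_mean, 1e-12)), 3)
  sel <- so$t > 0
  expect_lt(max(abs(so$var[sel] - expvar[sel]) / expvar[sel]), 0.05)
  # constant rates: stationary mean = production / gamma
  p2 <- cell_params(sigma_E = 0, omega = 0.01)
  so2 <- ssa_oracle(p2, schedule = rep(1, 40), n_reps = 5e3, seed = 7,
                    stochastic_E = FALSE)
  fss <- (p2$f0 + p2$k_F * p2$E_bar) / p2$gamma
  last <- nrow(so2)
  expect_lt(abs(so2$mean[last] - fss), 3 * so2$se_mean[last] + 0.01 * fss)
  expect_error(ssa_oracle(p2, 1, n_reps = 10), "at least 100")
})

test_that("division bookkeeping: threshold respected, log2 sawtooth unit drops", {
  p <- cell_params(sigma_E = 0, omega = 0, sigma_m = 0)
  st <- cell_state(H = 0, E = 1, F = 0, length = p$L0)
  lens <- numeric(200)
  for (i in 1:200) {
    st <- step_cell(st, p, u = 0, dt = 6)
    lens[i] <- st$length
    expect_lte(st$length, st$div_thresh)
  }
  drops <- diff(log2(lens))
  div_steps <- drops < -0.5
  expect_gt(sum(div_steps), 20)                  # ~25-min doubling
  # each division drop is one doubling minus one step of growth
  growth_per_step <- p$gamma * 6 / log(2)
  expect_equal(unname(drops[div_steps]), rep(-1 + growth_per_step,
                                             sum(div_steps)),
               tolerance = 1e-6)
})

test_that("rendered detection regions calibrate to the true fluorescence", {
  st <- cell_state(F = 15, E = 1, length = 2.5)
  set.seed(8)
  r <- render_detection_region(st)
  expect_equal(dim(r$image), c(80, 40))
  expect_equal(length(r$image), 3200)
  expect_identical(r$truth, 15)
  vals <- replicate(200, extract_fluorescence(render_detection_region(st)$image))
  expect_lt(abs(mean(vals) - 15) / 15, 0.02)
  expect_error(render_detection_region(st, width = 1), "degenerate")
})
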