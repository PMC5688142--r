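# Shared simulation helpers for the test suite. Everything is generated in
# code under fixed seeds; no stored fixtures.

# Simulate one cell whose dynamics exactly match the controller's model
# (E starts from its stationary distribution), returning the measurement
# record and the true latent states at measurement times.
simulate_matched_cell <- function(params, u_seq, dt = 6) {
  E <- max(0, rnorm(1, params$E_bar, params$sigma_E))
  H <- 0; F <- params$f0 / params$gamma
  len <- params$L0; dv <- 2 * params$L0
  K <- length(u_seq)
  y <- E_true <- F_true <- numeric(K)
  for (i in seq_len(K)) {
    r <- optoloop:::.step_engine(H, E, F, len, dv, u_seq[i], dt, params)
    H <- r$H; E <- r$E; F <- r$F; len <- r$len; dv <- r$div_thresh
    y[i] <- max(0, F + rnorm(1, 0, params$sigma_m))
    E_true[i] <- E; F_true[i] <- F
  }
  list(y = y, E_true = E_true, F_true = F_true)
}

# Histogram overlap coefficient of two samples on a common grid.
overlap_coef <- function(a, b, nbins = 30) {
  br <- seq(min(a, b) - 1, max(a, b) + 1, length.out = nbins)
  pa <- hist(a, br, plot = FALSE)$counts / length(a)
  pb <- hist(b, br, plot = FALSE)$counts / length(b)
  sum(pmin(pa, pb))
}

# Run a 4-cell ring of hybrid oscillators and return the per-seed median
# absolute neighbor phase lag (period-normalized).
ring_phase_lags <- function(mode, d, seed, f = 0.1, duration = 2400,
                            drop = 200, cv = 0.1) {
  Tm <- ring_transfer_matrix(4, f, mode)
  pop <- init_population(population_spec(4, cv = cv, seed = seed))
  log <- run_hybrid_experiment(hybrid_params(d = d, T = Tm), duration, pop,
                               seed = seed + 100)
  tr <- t(sapply(1:4, function(j) log$y[log$cell_id == j]))[, -(1:drop)]
  per <- median(unlist(lapply(1:4, function(j)
    diff(detect_expression_peaks(tr[j, ], dt = 6)))), na.rm = TRUE)
  median(abs(sapply(1:4, function(j)
    phase_lag(tr[j, ], tr[j %% 4 + 1, ], per, dt = 6))))
}

# Independent fixed-step Euler evaluation of the certainty-equivalent
# planning cost for a set of candidate binary sequences (matrix: candidates
# in rows). Used as the exhaustive-enumeration oracle for the planner.
oracle_plan_costs <- function(fs, cand, target, t, params, dt = 6,
                              h = 0.02) {
  nc <- nrow(cand); N <- ncol(cand)
  H <- rep(fs$H_now, nc); E <- rep(fs$mean[1], nc); F <- rep(fs$mean[2], nc)
  a <- 1 / params$tau_E
  cost <- numeric(nc)
  nstep <- round(dt / h)
  for (k in seq_len(N)) {
    u <- cand[, k]
    kH <- ifelse(u == 1, params$k_H, params$k_H_off)
    for (s in seq_len(nstep)) {
      dH <- kH * (u - H)
      dE <- a * (params$E_bar - E)
      dF <- params$f0 + params$k_F * E * H - params$gamma * F
      H <- H + h * dH; E <- E + h * dE; F <- F + h * dF
    }
    cost <- cost + (F - target$value(t + k * dt))^2
  }
  cost
}

# All binary sequences of length N as a matrix (rows = candidates).
all_sequences <- function(N) {
  as.matrix(expand.grid(rep(list(0:1), N)))[, N:1, drop = FALSE]
}
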