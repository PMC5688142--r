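# Stochastic virtual-cell simulator: three-state model (H, E, F) plus
# exponential growth with division. The engine below is vectorized over
# cells/replicates; `step_cell` is the single-cell interface.

# Vectorized stochastic substep integrator. H, E, F, len, div_thresh, u may
# be vectors of equal length; E_bar and gamma in `params` may be vectors of
# the same length (per-cell heterogeneity / perturbation). Uses the exact
# OU transition for E, analytic relaxation for H, Euler-Maruyama with
# Langevin noise for F (reflected at 0), and exponential length growth with
# division at the per-cell threshold.
.step_engine <- function(H, E, F, len, div_thresh, u, dt, params,
                         substep = 0.1, division_noise = 0.05) {
  n_sub <- max(1L, ceiling(dt / substep))
  h <- dt / n_sub
  tau_E <- params$tau_E; sigma_E <- params$sigma_E
  k_F <- params$k_F; f0 <- params$f0; omega <- params$omega
  E_bar <- params$E_bar; gamma <- params$gamma; L0 <- params$L0
  n <- length(F)
  k_H <- .kH_of(params, u)          # green and red switching rates differ
  rho <- exp(-h / tau_E)
  ou_sd <- sigma_E * sqrt(1 - rho^2)
  eH <- exp(-k_H * h)
  hbar_w <- (1 - eH) / (k_H * h)    # substep-average weight of the H decay
  eg <- exp(-gamma * h)
  gfac <- exp(gamma * h)            # length growth factor (possibly vector)
  for (s in seq_len(n_sub)) {
    # production evaluated at the substep-averaged H (analytic average of the
    # exponential relaxation), then exact exponential-decay update of the
    # conditional mean; Langevin noise added on top
    Hbar <- u + (H - u) * hbar_w
    prod <- f0 + k_F * E * Hbar
    Fdet <- F * eg + prod * (1 - eg) / gamma
    if (omega > 0) {
      noise <- sqrt(pmax(omega * (prod + gamma * F), 0) * h) * stats::rnorm(n)
    } else noise <- 0
    F <- abs(Fdet + noise)                    # reflect at 0
    E <- abs(E_bar + (E - E_bar) * rho + if (ou_sd > 0) ou_sd * stats::rnorm(n) else 0)
    H <- u + (H - u) * eH
    len <- len * gfac
    div <- len > div_thresh
    if (any(div)) {
      len[div] <- len[div] / 2
      nd <- sum(div)
      newt <- 2 * L0 * (1 + division_noise * stats::rnorm(nd))
      div_thresh[div] <- pmax(newt, 1.2 * L0)
    }
  }
  list(H = H, E = E, F = F, len = len, div_thresh = div_thresh)
}

#' Advance one virtual cell over a control interval
#'
#' Integrates the stochastic three-state model over `dt` minutes under a
#' constant binary light input: `H` relaxes exponentially toward `u`, at
#' rate `k_H` under green light and `k_H_off` under red; `E` follows an
#' Ornstein-Uhlenbeck process with mean `E_bar`,
#' relaxation time `tau_E` and stationary s.d. `sigma_E` (reflected at 0);
#' `F` integrates production `f0 + k_F * E * H` minus dilution `gamma * F`
#' with chemical-Langevin noise of intensity `omega * (production +
#' dilution)` (reflected at 0). Cell length grows exponentially at rate
#' `gamma` and halves at the division threshold (redrawn with 5%
#' multiplicative noise around `2 * L0`); fluorescence is treated as a
#' concentration-like readout and is not halved at division.
#'
#' Internal sub-stepping (default 0.1 min) is fine enough that halving it
#' changes ensemble moments by well under 1%.
#'
#' @param state a [cell_state()].
#' @param params a [cell_params()].
#' @param u binary light input: 0 = red (deactivating), 1 = green
#'   (activating).
#' @param dt interval length (min), default one 6-min control interval.
#' @param substep integration substep (min).
#'
#' @return The updated [cell_state()].
#' @export
step_cell <- function(state, params, u, dt = 6, substep = 0.1) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  if (!u %in% c(0, 1)) stop("light input u must be 0 (red) or 1 (green)")
  r <- .step_engine(state$H, state$E, state$F, state$length,
                    state$div_thresh, u, dt, params, substep = substep)
  cell_state(H = min(r$H, 1), E = r$E, F = r$F, length = r$len,
             t = state$t + dt, alive = state$alive,
             div_thresh = r$div_thresh)
}

#' Initialize a heterogeneous population of virtual cells
#'
#' Draws each cell's mean responsiveness `E_bar` from the log-normal
#' distribution implied by the spec's arithmetic mean and CV, and starts
#' every cell dark-adapted: `H = 0`, `E = E_bar`, and `F` at the no-light
#' steady state `f0 / gamma`. Deterministic under the spec's seed.
#'
#' @param spec a [population_spec()].
#' @return A list of `n_cells` elements, each `list(params, state)`.
#' @export
#' @examples
#' pop <- init_population(population_spec(5, cv = 0.3, seed = 7))
#' sapply(pop, function(cl) cl$params$E_bar)
init_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  tpl <- spec$template
  if (spec$cv == 0) {
    ebars <- rep(spec$mean, spec$n_cells)
  } else {
    sdlog <- sqrt(log(1 + spec$cv^2))
    meanlog <- log(spec$mean) - sdlog^2 / 2
    ebars <- stats::rlnorm(spec$n_cells, meanlog, sdlog)
  }
  lapply(seq_len(spec$n_cells), function(i) {
    p <- tpl
    p$E_bar <- ebars[i]
    st <- cell_state(H = 0, E = ebars[i], F = p$f0 / p$gamma,
                     length = p$L0, t = 0)
    list(params = p, state = st)
  })
}

#' Measure a cell's fluorescence
#'
#' Returns the cell's fluorescence plus zero-mean Gaussian technical noise of
#' s.d. `sigma_m`, truncated at 0.
#'
#' @param state a [cell_state()]; must be alive.
#' @param params a [cell_params()].
#' @return Measured fluorescence (a.u.).
#' @export
measure_cell <- function(state, params) {
  if (!isTRUE(state$alive)) stop("cannot measure a dead cell")
  if (params$sigma_m == 0) return(state$F)
  max(0, state$F + stats::rnorm(1, 0, params$sigma_m))
}

#' Apply a media perturbation to a cell's parameters
#'
#' For query times past the media switch plus the cell's transport lag, the
#' growth/dilution rate is stepped to `gamma_factor` times baseline; the mean
#' responsiveness ramps as
#' `E_bar * (1 + (resp_factor - 1) * (1 - exp(-max(0, t - t_switch -
#' resp_delay) / resp_tau)))`, so the expression-side effect emerges only
#' after `resp_delay` minutes. The function is a pure map from the baseline
#' parameters and the event, hence idempotent per time query.
#'
#' @param params baseline [cell_params()].
#' @param event a [perturbation_event()]; if its `lag` is `NULL` a lag is
#'   drawn once via [sample_transport_lag()] (pass an explicit `lag` for
#'   reproducible per-cell application).
#' @param t query time (min).
#' @return Possibly modified [cell_params()].
#' @export
apply_perturbation <- function(params, event, t) {
  stopifnot(t >= 0)
  lag <- event$lag
  if (is.null(lag)) lag <- sample_transport_lag(event)
  if (t < event$t_switch + lag) return(params)
  out <- params
  out$gamma <- params$gamma * event$gamma_factor
  dtr <- max(0, t - event$t_switch - event$resp_delay)
  ramp <- 1 + (event$resp_factor - 1) * (1 - exp(-dtr / event$resp_tau))
  out$E_bar <- params$E_bar * ramp
  out
}

#' Exact birth-death ensemble oracle for the fluorescence channel
#'
#' Independent validation oracle for the moment equations: simulates `F` as a
#' discrete birth-death process in molecule counts (production
#' `(f0 + k_F * E * H) / omega` molecules/min, first-order removal `gamma`
#' per molecule), with `E` and `H` frozen over fine substeps. Over each
#' frozen-rate substep the process is sampled from its exact transition law
#' (binomial survival of existing molecules plus Poisson immigration), so no
#' time-discretization error enters the `F` channel. Counts are converted to
#' intensity by `omega`.
#'
#' @param params a [cell_params()]; `omega` must be positive.
#' @param schedule integer vector of binary light inputs, one per interval.
#' @param dt interval length (min).
#' @param n_reps ensemble size (at least 100).
#' @param seed RNG seed.
#' @param substep frozen-rate substep (min, at most 0.1).
#' @param F0 initial fluorescence (a.u.); default `f0 / gamma`.
#' @param stochastic_E if `FALSE`, hold `E` at `E_bar` (deterministic rates).
#'
#' @return A data.frame with columns `t`, `mean`, `var`, `se_mean` giving
#'   ensemble statistics of `F` at the end of each interval (and at t = 0).
#' @export
ssa_oracle <- function(params, schedule, dt = 6, n_reps = 1e4, seed = 1L,
                       substep = 0.1, F0 = params$f0 / params$gamma,
                       stochastic_E = TRUE) {
  if (n_reps < 100) stop("n_reps must be at least 100 for a usable ensemble")
  if (params$omega <= 0) stop("ssa_oracle requires omega > 0 (molecule scale)")
  stopifnot(substep <= 0.1, all(schedule %in% c(0, 1)))
  set.seed(seed)
  omega <- params$omega; gamma <- params$gamma
  n_sub <- max(1L, ceiling(dt / substep)); h <- dt / n_sub
  surv <- exp(-gamma * h)
  rho <- exp(-h / params$tau_E)
  ou_sd <- params$sigma_E * sqrt(1 - rho^2)
  n <- round(rep(F0 / omega, n_reps))
  E <- rep(params$E_bar, n_reps); H <- rep(0, n_reps)
  out <- data.frame(t = 0, mean = mean(n) * omega, var = stats::var(n) * omega^2,
                    se_mean = stats::sd(n) * omega / sqrt(n_reps))
  t <- 0
  for (u in schedule) {
    kH <- .kH_of(params, u)
    eH <- exp(-kH * h)
    hbar_w <- (1 - eH) / (kH * h)
    for (s in seq_len(n_sub)) {
      Hbar <- u + (H - u) * hbar_w
      lam <- (params$f0 + params$k_F * E * Hbar) / omega   # molecules / min
      imm <- lam * (1 - surv) / gamma
      n <- stats::rbinom(n_reps, n, surv) + stats::rpois(n_reps, imm)
      if (stochastic_E && ou_sd > 0)
        E <- abs(params$E_bar + (E - params$E_bar) * rho +
                   ou_sd * stats::rnorm(n_reps))
      H <- u + (H - u) * eH
    }
    t <- t + dt
    Fv <- n * omega
    out <- rbind(out, data.frame(t = t, mean = mean(Fv), var = stats::var(Fv),
                                 se_mean = stats::sd(Fv) / sqrt(n_reps)))
  }
  rownames(out) <- NULL
  out
}

#' Ensemble statistics from replicate Langevin simulations
#'
#' Convenience wrapper running `n_reps` independent copies of the
#' [step_cell()] dynamics (vectorized) under a fixed stimulus schedule and
#' returning per-interval ensemble mean/variance of `F`. Used to validate
#' the moment equations.
#'
#' @inheritParams ssa_oracle
#' @param E0 initial responsiveness; default `E_bar`.
#' @return A data.frame with columns `t`, `mean`, `var`, `se_mean`,
#'   `se_var`.
#' @export
ensemble_moments <- function(params, schedule, dt = 6, n_reps = 1e4,
                             seed = 1L, substep = 0.1,
                             F0 = params$f0 / params$gamma,
                             E0 = params$E_bar) {
  stopifnot(all(schedule %in% c(0, 1)))
  set.seed(seed)
  H <- rep(0, n_reps); E <- rep(E0, n_reps); F <- rep(F0, n_reps)
  len <- rep(params$L0, n_reps); dv <- rep(2 * params$L0, n_reps)
  stat <- function(t, F) {
    v <- stats::var(F)
    # se of sample variance under approximate normality: var * sqrt(2/(n-1))
    data.frame(t = t, mean = mean(F), var = v,
               se_mean = stats::sd(F) / sqrt(n_reps),
               se_var = v * sqrt(2 / (n_reps - 1)))
  }
  out <- stat(0, F)
  t <- 0
  for (u in schedule) {
    r <- .step_engine(H, E, F, len, dv, u, dt, params, substep = substep)
    H <- r$H; E <- r$E; F <- r$F; len <- r$len; dv <- r$div_thresh
    t <- t + dt
    out <- rbind(out, stat(t, F))
  }
  rownames(out) <- NULL
  out
}

#' Render a synthetic detection-region image
#'
#' Produces the kind of raw input the imaging pipeline sees: a fixed
#' bounding box (default 40 x 80 pixels) containing background pixels at a
#' baseline plus Gaussian noise, and a rod-shaped foreground of bright
#' pixels calibrated so that the nearest-rank 97th-percentile readout
#' ([extract_fluorescence()]) equals the cell's true fluorescence in
#' expectation: with `m` foreground pixels of s.d. `fg_sd`, their mean is
#' offset by `-fg_sd * qnorm(1 - n_above/m)` where `n_above` is the number
#' of pixels above the extracted rank.
#'
#' @param state a [cell_state()]; its `F` is the ground truth readout.
#' @param width,height box dimensions in pixels.
#' @param background background intensity baseline (a.u.).
#' @param bg_sd background noise s.d. (a.u.).
#' @param fg_sd foreground pixel noise s.d. (a.u.).
#' @param cell_px number of foreground pixels (default 192, i.e. twice the
#'   3% tail of a 40 x 80 box).
#'
#' @return A list with `image` (a `height` x `width` matrix) and
#'   `truth` (the ground-truth fluorescence).
#' @export
render_detection_region <- function(state, width = 40, height = 80,
                                    background = 0.5, bg_sd = 0.05,
                                    fg_sd = 0.25, cell_px = 192) {
  if (width < 2 || height < 2) stop("degenerate detection-region geometry")
  npix <- width * height
  if (cell_px >= npix) stop("foreground larger than region")
  n_above <- npix - ceiling(0.97 * npix)      # pixels above the extracted rank
  if (cell_px <= n_above)
    stop("foreground must exceed the percentile tail size")
  img <- matrix(background + stats::rnorm(npix, 0, bg_sd), height, width)
  # rod-shaped mask: centred rectangle, width ~ cell width, length giving
  # cell_px pixels
  w_cell <- max(2L, min(width, round(sqrt(cell_px / 3))))
  l_cell <- ceiling(cell_px / w_cell)
  rows <- seq(max(1, floor((height - l_cell) / 2) + 1), length.out = l_cell)
  cols <- seq(max(1, floor((width - w_cell) / 2) + 1), length.out = w_cell)
  mask <- as.matrix(expand.grid(rows, cols))[seq_len(cell_px), , drop = FALSE]
  mu <- state$F - fg_sd * stats::qnorm(1 - n_above / cell_px)
  img[mask] <- mu + stats::rnorm(cell_px, 0, fg_sd)
  img[img < 0] <- 0
  list(image = img, truth = state$F)
}
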