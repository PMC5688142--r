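# Moment-equation propagation of (E, F) means and covariances, and the
# Kalman measurement update that turns fluorescence readings into estimates
# of latent cell responsiveness. H is treated as known: it evolves
# deterministically from the applied light history, which makes the filter
# exact for the conditionally linear-Gaussian model.

#' Controller-side belief state over a cell's (E, F)
#'
#' @param mean numeric 2-vector: posterior mean of (E, F) (a.u.).
#' @param cov 2x2 symmetric positive-semidefinite covariance (a.u.^2).
#' @param t time (min).
#' @param H_now current (deterministic) promoter activation in `[0, 1]`.
#' @return An object of class `filter_state`.
#' @export
filter_state <- function(mean, cov, t = 0, H_now = 0) {
  mean <- as.numeric(mean)
  cov <- matrix(as.numeric(cov), 2, 2)
  if (length(mean) != 2L) stop("mean must have length 2 (E, F)")
  if (max(abs(cov - t(cov))) > 1e-8 * (1 + max(abs(cov))))
    stop("covariance must be symmetric")
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(ev)))
    stop("covariance must be positive semidefinite")
  structure(list(mean = mean, cov = cov, t = t, H_now = H_now),
            class = "filter_state")
}

#' Default filter initialization for a cell
#'
#' Responsiveness starts at the population mean with variance `sigma_E^2`;
#' fluorescence at the first measurement (or the dark steady state) with
#' variance `sigma_m^2`.
#'
#' @param params a [cell_params()] (the controller's nominal model).
#' @param y0 first measurement (a.u.); default dark steady state.
#' @param t time (min).
#' @return A [filter_state()].
#' @export
init_filter <- function(params, y0 = params$f0 / params$gamma, t = 0) {
  filter_state(mean = c(params$E_bar, y0),
               cov = diag(c(params$sigma_E^2, params$sigma_m^2)),
               t = t, H_now = 0)
}

# Closed-form propagation of the mean (E, F, H) under constant input u over
# dt minutes. Vectorized over states; used by the receding-horizon planner
# where only expected fluorescence enters the cost.
.mean_step <- function(H, E, F, u, dt, params) {
  a <- 1 / params$tau_E; g <- params$gamma; kH <- .kH_of(params, u)
  kF <- params$k_F; f0 <- params$f0; Eb <- params$E_bar
  conv <- function(lam) { # int_0^dt exp(-g (dt - s)) exp(-lam s) ds
    d <- g - lam
    ifelse(abs(d) < 1e-12, dt * exp(-g * dt),
           (exp(-lam * dt) - exp(-g * dt)) / d)
  }
  c0 <- f0 + kF * Eb * u
  c1 <- kF * Eb * (H - u)          # decays at kH
  c2 <- kF * (E - Eb) * u          # decays at a
  c3 <- kF * (E - Eb) * (H - u)    # decays at a + kH
  Fn <- F * exp(-g * dt) + c0 * conv(0) + c1 * conv(kH) +
    c2 * conv(a) + c3 * conv(a + kH)
  list(H = u + (H - u) * exp(-kH * dt),
       E = Eb + (E - Eb) * exp(-a * dt),
       F = Fn)
}

#' Propagate prediction mean and uncertainty by moment equations
#'
#' Integrates the coupled first/second-moment ODEs of the (E, F) system with
#' `H(t)` advanced deterministically from `H_now` under the binary input `u`:
#' \deqn{d m/dt = A(t) m + c, \quad dV/dt = A V + V A^T + Q(t)}
#' with `A(t) = [[-1/tau_E, 0], [k_F H(t), -gamma]]`,
#' `c = (E_bar / tau_E, f0)`, and process noise
#' `Q(t) = diag(2 sigma_E^2 / tau_E, omega (f0 + k_F H(t) m_E + gamma m_F))`
#' from the OU and chemical-Langevin intensities. Uses an adaptive
#' stiff-capable integrator (`deSolve::lsoda`) at tight tolerance.
#'
#' @param fs a [filter_state()] (prior at time `fs$t`).
#' @param u binary light input over the interval.
#' @param dt interval length (min).
#' @param params a [cell_params()].
#' @return The predicted [filter_state()] at `fs$t + dt`.
#' @export
propagate_moments <- function(fs, u, dt, params) {
  if (dt <= 0) stop("dt must be positive")
  if (!u %in% c(0, 1)) stop("light input u must be 0 or 1")
  a <- 1 / params$tau_E; g <- params$gamma
  kF <- params$k_F; kH <- .kH_of(params, u)
  H0 <- fs$H_now
  rhs <- function(t, y, p) {
    H <- u + (H0 - u) * exp(-kH * t)
    mE <- y[1]; mF <- y[2]; V11 <- y[3]; V12 <- y[4]; V22 <- y[5]
    q22 <- params$omega * (params$f0 + kF * H * mE + g * mF)
    list(c(a * (params$E_bar - mE),
           params$f0 + kF * H * mE - g * mF,
           -2 * a * V11 + 2 * params$sigma_E^2 * a,
           kF * H * V11 - (a + g) * V12,
           2 * kF * H * V12 - 2 * g * V22 + q22))
  }
  y0 <- c(fs$mean, fs$cov[1, 1], fs$cov[1, 2], fs$cov[2, 2])
  sol <- deSolve::lsoda(y0, c(0, dt), rhs, parms = NULL,
                        rtol = 1e-9, atol = 1e-11)
  y <- sol[nrow(sol), -1]
  cov <- matrix(c(y[3], y[4], y[4], y[5]), 2, 2)
  cov[cov < 0 & abs(cov) < 1e-14] <- 0
  filter_state(mean = pmax(y[1:2], 0), cov = cov, t = fs$t + dt,
               H_now = u + (H0 - u) * exp(-kH * dt))
}

#' Kalman measurement update of the (E, F) belief
#'
#' Standard linear-Gaussian update with the observation picking the `F`
#' component: the prediction and the measurement are combined with weights
#' set by their respective uncertainties. The responsiveness estimate moves
#' only through the E-F covariance. Posterior means are clamped at 0;
#' the covariance is left untouched.
#'
#' @param predicted a [filter_state()] from [propagate_moments()].
#' @param y measured fluorescence (a.u.).
#' @param sigma_m measurement noise s.d. (a.u.).
#' @return The posterior [filter_state()].
#' @export
kalman_update <- function(predicted, y, sigma_m) {
  if (sigma_m < 0) stop("sigma_m must be non-negative")
  V <- predicted$cov
  S <- V[2, 2] + sigma_m^2
  if (S <= 0) return(predicted)      # degenerate: no information either way
  K <- c(V[1, 2], V[2, 2]) / S
  mean <- predicted$mean + K * (y - predicted$mean[2])
  cov <- V - outer(K, c(V[1, 2], V[2, 2]))
  cov <- (cov + t(cov)) / 2
  filter_state(mean = pmax(mean, 0), cov = cov, t = predicted$t,
               H_now = predicted$H_now)
}

#' Estimate a cell's responsiveness trajectory from its record
#'
#' Runs the predict/update cycle over an aligned record of measurements and
#' applied stimuli and returns the per-interval posterior mean and s.d. of
#' the latent responsiveness `E`.
#'
#' @param y numeric vector of measured fluorescence, one per interval
#'   (measurement at the end of the interval during which `u` was applied).
#' @param u integer vector of binary stimuli, same length as `y`.
#' @param params a [cell_params()] (nominal model).
#' @param dt interval length (min).
#' @param fs0 optional initial [filter_state()]; default [init_filter()].
#' @return A data.frame with columns `t`, `E_hat`, `E_sd`, `F_hat`,
#'   `innovation` (measurement minus one-step prediction) and `innovation_sd`.
#' @export
estimate_responsiveness <- function(y, u, params, dt = 6, fs0 = NULL) {
  if (length(y) != length(u)) stop("y and u must have equal length")
  fs <- if (is.null(fs0)) init_filter(params) else fs0
  n <- length(y)
  out <- data.frame(t = numeric(n), E_hat = numeric(n), E_sd = numeric(n),
                    F_hat = numeric(n), innovation = numeric(n),
                    innovation_sd = numeric(n))
  for (i in seq_len(n)) {
    pred <- propagate_moments(fs, u[i], dt, params)
    S <- pred$cov[2, 2] + params$sigma_m^2
    fs <- kalman_update(pred, y[i], params$sigma_m)
    out$t[i] <- fs$t
    out$E_hat[i] <- fs$mean[1]
    out$E_sd[i] <- sqrt(max(fs$cov[1, 1], 0))
    out$F_hat[i] <- fs$mean[2]
    out$innovation[i] <- y[i] - pred$mean[2]
    out$innovation_sd[i] <- sqrt(S)
  }
  out
}
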