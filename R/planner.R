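# Receding-horizon planning over binary light sequences: exhaustive
# enumeration of all 2^N candidate sequences, propagating the predicted mean
# fluorescence with the closed-form solution of the mean equations
# (certainty-equivalent cost over expected levels).

#' Plan the best binary light sequence over a finite horizon
#'
#' Enumerates all `2^N` binary stimulus sequences over the next `N` control
#' intervals, propagates the predicted mean fluorescence for each, and
#' returns the sequence minimizing the squared deviation from the target:
#' \deqn{cost = \sum_{k=1}^{N} (E[F(t + k \Delta)] - target(t + k \Delta))^2}
#' Ties are broken toward the sequence with fewer green (activating)
#' intervals, then lexicographically red-first, so planning is fully
#' deterministic.
#'
#' The cost is certainty-equivalent (expected levels only); an optional
#' variance penalty adds `var_weight` times the predicted `F` variance at
#' each step, computed from the moment equations.
#'
#' @param fs a [filter_state()] (current belief at time `t`).
#' @param target a [make_target_profile()].
#' @param t current time (min).
#' @param N planning horizon in intervals (at most 12).
#' @param params a [cell_params()] (controller's model; `E_bar` is taken
#'   from the belief for prediction, i.e. the mean `E` relaxes toward the
#'   nominal `E_bar`).
#' @param dt control interval (min).
#' @param var_weight weight of the predicted-variance penalty (default 0,
#'   the certainty-equivalent cost).
#'
#' @return An object of class `control_plan`: list with `sequence` (integer
#'   vector of 0/1 stimuli), `cost`, and `predicted` (mean F along the chosen
#'   sequence).
#' @export
plan_receding_horizon <- function(fs, target, t, N = 8, params, dt = 6,
                                  var_weight = 0) {
  if (N < 1) stop("planning horizon must be at least 1 interval")
  if (N > 12) stop("horizon > 12 would enumerate more than 4096 sequences")
  H <- fs$H_now; E <- fs$mean[1]; F <- fs$mean[2]
  cost <- 0; greens <- 0
  seqs <- matrix(integer(0), nrow = 1, ncol = 0)
  vpen <- NULL
  if (var_weight > 0) vpen <- list(fs = list(fs))
  for (k in seq_len(N)) {
    # branch: each candidate splits into (red, green), red child first so the
    # final ordering is lexicographic with red < green, first interval most
    # significant
    H <- rep(H, each = 2); E <- rep(E, each = 2); F <- rep(F, each = 2)
    cost <- rep(cost, each = 2); greens <- rep(greens, each = 2)
    seqs <- seqs[rep(seq_len(nrow(seqs)), each = 2), , drop = FALSE]
    u <- rep_len(c(0L, 1L), length(F))
    st <- .mean_step(H, E, F, u, dt, params)
    H <- st$H; E <- st$E; F <- st$F
    tgt <- target$value(t + k * dt)
    cost <- cost + (F - tgt)^2
    greens <- greens + u
    seqs <- cbind(seqs, u)
    if (!is.null(vpen)) {
      vpen$fs <- unlist(lapply(vpen$fs, function(f) {
        list(propagate_moments(f, 0, dt, params),
             propagate_moments(f, 1, dt, params))
      }), recursive = FALSE)
      cost <- cost + var_weight *
        vapply(vpen$fs, function(f) f$cov[2, 2], numeric(1))
    }
  }
  ord <- order(cost, greens, seq_along(cost))
  best <- ord[1]
  # recover predicted mean trajectory of the winning sequence
  seq_best <- as.integer(seqs[best, ])
  Hb <- fs$H_now; Eb <- fs$mean[1]; Fb <- fs$mean[2]
  pred <- numeric(N)
  for (k in seq_len(N)) {
    st <- .mean_step(Hb, Eb, Fb, seq_best[k], dt, params)
    Hb <- st$H; Eb <- st$E; Fb <- st$F
    pred[k] <- Fb
  }
  structure(list(sequence = seq_best, cost = cost[best], predicted = pred),
            class = "control_plan")
}

#' Precompute an open-loop stimulus sequence from the nominal model
#'
#' Runs the receding-horizon planner against the deterministic nominal
#' ("average cell") model for the whole experiment: at each interval the
#' planner's own mean prediction serves as the surrogate measurement, the
#' first stimulus of the plan is recorded, and the nominal state is advanced
#' under it. The resulting sequence is fixed and broadcast identically to
#' every assigned cell, with no online learning or feedback.
#'
#' @param target a [make_target_profile()].
#' @param nominal a [cell_params()] identified from calibration data.
#' @param duration experiment duration (min), a multiple of `dt`.
#' @param N planning horizon (intervals).
#' @param dt control interval (min).
#' @param fs0 optional initial [filter_state()]; default nominal dark state.
#' @return Integer vector of `duration / dt` binary stimuli.
#' @export
precompute_ol_sequence <- function(target, nominal, duration, N = 8, dt = 6,
                                   fs0 = NULL) {
  K <- duration / dt
  if (abs(K - round(K)) > 1e-9) stop("duration must be a multiple of dt")
  K <- as.integer(round(K))
  fs <- if (is.null(fs0)) {
    filter_state(c(nominal$E_bar, nominal$f0 / nominal$gamma),
                 matrix(0, 2, 2), t = 0, H_now = 0)
  } else fs0
  out <- integer(K)
  H <- fs$H_now; E <- fs$mean[1]; F <- fs$mean[2]; t <- fs$t
  for (i in seq_len(K)) {
    fsi <- filter_state(c(E, F), matrix(0, 2, 2), t = t, H_now = H)
    plan <- plan_receding_horizon(fsi, target, t, N = min(N, K - i + 1),
                                  params = nominal, dt = dt)
    u <- plan$sequence[1]
    st <- .mean_step(H, E, F, u, dt, nominal)
    H <- st$H; E <- st$E; F <- st$F; t <- t + dt
    out[i] <- u
  }
  out
}
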