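# The three control modes: open loop (OL, precomputed broadcast sequence),
# population-level closed loop (pCL, one shared filter fed by the population
# median), and individual-level closed loop (iCL, one filter and one planned
# sequence per cell).

#' One individual-level closed-loop (iCL) controller step
#'
#' Called once per 6-min interval per cell: updates the cell's belief with
#' the new measurement ([kalman_update()]), plans the best light sequence
#' from the posterior ([plan_receding_horizon()]), emits the first stimulus
#' of the plan, and advances the belief under that stimulus
#' ([propagate_moments()]).
#'
#' @param fs the cell's predicted [filter_state()] at measurement time.
#' @param y the new fluorescence measurement (a.u.).
#' @param target a [make_target_profile()].
#' @param t current time (min).
#' @param params controller's nominal [cell_params()].
#' @param N planning horizon (intervals).
#' @param dt control interval (min).
#' @return A list with `stimulus` (0/1), `filter` (the belief advanced to
#'   `t + dt`), `posterior` (the belief after the update, before advancing)
#'   and `plan`.
#' @export
icl_step <- function(fs, y, target, t, params, N = 8, dt = 6) {
  post <- kalman_update(fs, y, params$sigma_m)
  plan <- plan_receding_horizon(post, target, t, N = N, params = params,
                                dt = dt)
  u <- plan$sequence[1]
  list(stimulus = u,
       filter = propagate_moments(post, u, dt, params),
       posterior = post, plan = plan)
}

#' One population-level closed-loop (pCL) controller step
#'
#' Summarizes the valid, non-blocked cells' measurements, updates a single
#' shared filter, plans one sequence, and broadcasts its first stimulus to
#' all cells. Cells flagged by [detect_runaway()] are excluded from the
#' summary but still receive the broadcast stimulus. The default summary is
#' the mean of the contributing cells -- a pCL controller's objective is to
#' remove errors in the population mean, and robustness against extreme
#' cells is already provided by the runaway blocking -- with the median
#' available as a more conservative option.
#'
#' @param ys numeric vector of the population's measurements (a.u.).
#' @param fs the shared predicted [filter_state()].
#' @param target a [make_target_profile()].
#' @param t current time (min).
#' @param params controller's nominal [cell_params()].
#' @param valid logical vector: cells eligible for the summary (default all).
#' @param blocked logical vector: runaway-blocked cells (default none).
#' @param N planning horizon (intervals).
#' @param dt control interval (min).
#' @param summary `"mean"` (default) or `"median"`.
#' @return As [icl_step()], plus `summary` (the statistic used).
#' @export
pcl_step <- function(ys, fs, target, t, params, valid = NULL, blocked = NULL,
                     N = 8, dt = 6, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  if (is.null(valid)) valid <- rep(TRUE, length(ys))
  if (is.null(blocked)) blocked <- rep(FALSE, length(ys))
  use <- valid & !blocked
  if (!any(use)) stop("pCL step requires at least one valid, non-blocked cell")
  y_sum <- if (summary == "mean") mean(ys[use]) else stats::median(ys[use])
  out <- icl_step(fs, y_sum, target, t, params, N = N, dt = dt)
  out$summary <- y_sum
  out
}
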