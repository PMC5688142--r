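# Orchestrates the 6-min measure -> estimate -> plan -> stimulate loop over
# a simulated population with mixed controller assignments (OL / pCL / iCL /
# hybrid), media perturbation events, online runaway blocking and optional
# online invalidation. Within an interval, measurement always precedes the
# stimulus decision, and the decided stimulus applies over the following
# interval.

#' Configure a closed-loop control experiment
#'
#' @param duration experiment duration (min), a multiple of `interval`.
#' @param population a [population_spec()].
#' @param assignments list of controller assignments. Each assignment is a
#'   list with fields:
#'   \describe{
#'     \item{cells}{integer vector of cell indices.}
#'     \item{type}{one of `"OL"`, `"pCL"`, `"iCL"`, `"hybrid"`, `"none"`.}
#'     \item{target}{a [make_target_profile()] shared by the group, or
#'       `targets`: a list with one profile per cell (iCL only).}
#'     \item{switch}{optional `list(t = , type = )`: the group switches
#'       controller type at time `t` (e.g. OL until 780 min, then iCL).}
#'     \item{hybrid}{a [hybrid_params()] (hybrid groups only).}
#'   }
#' @param interval control interval (min, default 6).
#' @param perturbations list of [perturbation_event()]s.
#' @param seed integer seed governing every random draw of the run.
#' @param horizon planning horizon (intervals).
#' @param qc list: `enabled` (online invalidation, default `FALSE`),
#'   `thresholds` and `persistence` as in [classify_validity()],
#'   `runaway_c` (MAD multiplier for pCL blocking), `default_stimulus`
#'   (applied to invalidated cells, 0 = red).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(duration, population, assignments,
                              interval = 6, perturbations = list(),
                              seed = 1L, horizon = 8,
                              qc = list()) {
  K <- duration / interval
  if (abs(K - round(K)) > 1e-9)
    stop("duration must be a multiple of the control interval")
  stopifnot(inherits(population, "population_spec"))
  n <- population$n_cells
  owner <- integer(n)
  for (a in seq_along(assignments)) {
    as_ <- assignments[[a]]
    if (is.null(as_$cells) || is.null(as_$type))
      stop("each assignment needs 'cells' and 'type'")
    if (!as_$type %in% c("OL", "pCL", "iCL", "hybrid", "none"))
      stop("unknown controller type: ", as_$type)
    if (any(as_$cells < 1 | as_$cells > n))
      stop("assignment references cells outside the population")
    if (any(owner[as_$cells] != 0))
      stop("every cell must be assigned exactly one controller")
    owner[as_$cells] <- a
  }
  if (any(owner == 0))
    stop("every cell must be assigned exactly one controller")
  qc_def <- list(enabled = FALSE,
                 thresholds = list(growth_min = 0.2, reporter_min = 1,
                                   resp_min = 0.1),
                 persistence = 3, runaway_c = 5, default_stimulus = 0L)
  qc <- utils::modifyList(qc_def, qc)
  structure(list(duration = duration, interval = interval,
                 population = population, assignments = assignments,
                 perturbations = perturbations, seed = as.integer(seed),
                 horizon = horizon, qc = qc),
            class = "experiment_config")
}

# effective controller type of an assignment at time t
.assignment_type <- function(as_, t) {
  ty <- as_$type
  if (!is.null(as_$switch) && t >= as_$switch$t) ty <- as_$switch$type
  ty
}

# per-cell target profile lookup for an assignment
.assignment_target <- function(as_, local_idx) {
  if (!is.null(as_$targets)) as_$targets[[local_idx]] else as_$target
}

#' Run a control experiment on a simulated population
#'
#' Executes the full measurement-and-control loop: every interval each cell
#' is advanced under its last stimulus, measured, the controllers update
#' their estimates and decide the next stimuli, and everything is logged.
#' Media perturbation events modify the cells' growth rate and mean
#' responsiveness by time (the controllers' nominal model is deliberately
#' unaware of them). Fully deterministic given the config's seed.
#'
#' @param config an [experiment_config()].
#' @return An `experiment_log`: a data.frame with one row per cell per
#'   interval (columns `cell_id`, `interval`, `t`, `y`, `F_true`, `E_true`,
#'   `H_true`, `length`, `stimulus` (`"R"`/`"G"`, applied during the
#'   interval ending at `t`), `controller`, `target`, `E_hat`, `E_sd`,
#'   `F_hat`, `S`, `P`, `valid`, `blocked`), with attributes `config` and
#'   `seed`. Zero duration gives an empty log with metadata only.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dt <- config$interval
  K <- as.integer(round(config$duration / dt))
  set.seed(config$seed)
  pop <- init_population(config$population)   # reseeds with population seed
  set.seed(config$seed + 1L)                  # driving noise stream
  n <- length(pop)
  nominal <- config$population$template
  nominal$E_bar <- config$population$mean
  N <- config$horizon
  qc <- config$qc

  empty <- data.frame(cell_id = integer(0), interval = integer(0),
                      t = numeric(0), y = numeric(0), F_true = numeric(0),
                      E_true = numeric(0), H_true = numeric(0),
                      length = numeric(0), stimulus = character(0),
                      controller = character(0), target = numeric(0),
                      E_hat = numeric(0), E_sd = numeric(0),
                      F_hat = numeric(0), S = numeric(0), P = logical(0),
                      valid = logical(0), blocked = logical(0))
  if (K == 0L) {
    attr(empty, "config") <- config; attr(empty, "seed") <- config$seed
    class(empty) <- c("experiment_log", "data.frame")
    return(empty)
  }

  # materialize per-cell perturbation lags once
  events <- lapply(config$perturbations, function(ev) {
    lags <- sample_transport_lag(ev, n)
    lapply(seq_len(n), function(i) { e <- ev; e$lag <- lags[i]; e })
  })

  # per-assignment controller state
  ctrl <- lapply(config$assignments, function(as_) {
    st <- list(as_ = as_)
    types <- unique(c(as_$type, if (!is.null(as_$switch)) as_$switch$type))
    if ("OL" %in% types) {
      # one precomputed sequence per distinct target in the group
      st$ol_seq <- lapply(seq_along(as_$cells), function(j)
        precompute_ol_sequence(.assignment_target(as_, j), nominal,
                               duration = K * dt, N = N, dt = dt))
    }
    if (any(c("iCL") %in% types)) {
      st$fs <- lapply(seq_along(as_$cells), function(j)
        propagate_moments(init_filter(nominal), 0, dt, nominal))
    }
    if ("pCL" %in% types)
      st$fs_shared <- propagate_moments(init_filter(nominal), 0, dt, nominal)
    if ("hybrid" %in% types) {
      st$S <- rep(0, length(as_$cells))
      st$P <- rep(TRUE, length(as_$cells))
    }
    st
  })

  # vectorized cell state
  H <- vapply(pop, function(cl) cl$state$H, numeric(1))
  E <- vapply(pop, function(cl) cl$state$E, numeric(1))
  F <- vapply(pop, function(cl) cl$state$F, numeric(1))
  len <- vapply(pop, function(cl) cl$state$length, numeric(1))
  dth <- vapply(pop, function(cl) cl$state$div_thresh, numeric(1))
  ebar0 <- vapply(pop, function(cl) cl$params$E_bar, numeric(1))
  gamma0 <- rep(nominal$gamma, n)
  u <- rep(0L, n)                       # dark until first decisions
  if (length(ctrl)) for (a in seq_along(ctrl)) { # OL sequences start at interval 1
    as_ <- config$assignments[[a]]
    if (.assignment_type(as_, 0) == "OL")
      u[as_$cells] <- vapply(seq_along(as_$cells),
                             function(j) ctrl[[a]]$ol_seq[[j]][1], integer(1))
  }
  valid <- rep(TRUE, n); blocked <- rep(FALSE, n)
  fail_run <- rep(0L, n)
  lenhist <- matrix(NA_real_, K + 1, n); lenhist[1, ] <- len

  out <- vector("list", K)
  for (i in seq_len(K)) {
    t_meas <- i * dt
    # perturbed parameters for this interval (evaluated at its start)
    E_bar_i <- ebar0; gamma_i <- gamma0
    for (evs in events) for (j in seq_len(n)) {
      base <- nominal; base$E_bar <- ebar0[j]
      pj <- apply_perturbation(base, evs[[j]], t_meas - dt)
      E_bar_i[j] <- pj$E_bar; gamma_i[j] <- pj$gamma
    }
    pv <- nominal; pv$E_bar <- E_bar_i; pv$gamma <- gamma_i
    st <- .step_engine(H, E, F, len, dth, u, dt, pv)
    H <- pmin(st$H, 1); E <- st$E; F <- st$F; len <- st$len
    dth <- st$div_thresh
    lenhist[i + 1, ] <- len
    y <- if (nominal$sigma_m > 0)
      pmax(0, F + stats::rnorm(n, 0, nominal$sigma_m)) else F

    # online QC: growth-based invalidation (absorbing)
    if (isTRUE(qc$enabled) && i >= 6) {
      gr <- apply(lenhist[max(1, i - 9):(i + 1), , drop = FALSE], 2,
                  function(L) {
                    L <- L[!is.na(L)]
                    if (length(L) < 6) return(NA_real_)
                    g <- estimate_growth_rate(L, dt = dt)
                    g[length(g)]
                  })
      failing <- !is.na(gr) & gr < qc$thresholds$growth_min
      fail_run <- ifelse(failing, fail_run + 1L, 0L)
      valid <- valid & !(fail_run >= qc$persistence)
    }

    E_hat <- rep(NA_real_, n); E_sd <- rep(NA_real_, n)
    F_hat <- rep(NA_real_, n); Sv <- rep(NA_real_, n); Pv <- rep(NA, n)
    ctype <- character(n); tgt <- rep(NA_real_, n)
    u_next <- u

    for (a in seq_along(ctrl)) {
      as_ <- config$assignments[[a]]
      cells <- as_$cells
      ty <- .assignment_type(as_, t_meas)
      ty_prev <- .assignment_type(as_, t_meas - dt)
      ctype[cells] <- ty
      if (ty %in% c("OL", "pCL", "iCL"))
        tgt[cells] <- vapply(seq_along(cells), function(j)
          .assignment_target(as_, j)$value(t_meas), numeric(1))
      if (ty == "none") { u_next[cells] <- qc$default_stimulus; next }
      if (ty == "hybrid") {
        hp <- as_$hybrid
        S <- ctrl[[a]]$S
        if (isTRUE(hp$transfer_first) && !is.null(hp$T))
          S <- apply_transfer(S, hp$T, clamp = hp$clamp)
        S <- update_virtual_signal(S, y[cells], hp$r, hp$d)
        if (!isTRUE(hp$transfer_first) && !is.null(hp$T))
          S <- apply_transfer(S, hp$T, clamp = hp$clamp)
        ps <- promoter_states(as.numeric(S), hp$theta)
        ctrl[[a]]$S <- as.numeric(S); ctrl[[a]]$P <- ps$P
        Sv[cells] <- as.numeric(S); Pv[cells] <- ps$P
        u_next[cells] <- ps$stimuli
        next
      }
      if (ty == "iCL") {
        if (ty_prev != "iCL") {
          # (re)initialize per-cell filters at the switch, seeded from the
          # current measurements
          ctrl[[a]]$fs <- lapply(seq_along(cells), function(j) {
            fs <- init_filter(nominal, y0 = y[cells[j]], t = t_meas - dt)
            fs$H_now <- H[cells[j]]  # H is known from the light history
            propagate_moments(fs, u[cells[j]], dt, nominal)
          })
        }
        for (j in seq_along(cells)) {
          cj <- cells[j]
          if (!valid[cj]) { u_next[cj] <- qc$default_stimulus; next }
          stp <- icl_step(ctrl[[a]]$fs[[j]], y[cj],
                          .assignment_target(as_, j), t_meas, nominal,
                          N = N, dt = dt)
          ctrl[[a]]$fs[[j]] <- stp$filter
          u_next[cj] <- stp$stimulus
          E_hat[cj] <- stp$posterior$mean[1]
          E_sd[cj] <- sqrt(max(stp$posterior$cov[1, 1], 0))
          F_hat[cj] <- stp$posterior$mean[2]
        }
      } else if (ty == "pCL") {
        if (ty_prev != "pCL")
          ctrl[[a]]$fs_shared <- propagate_moments(
            init_filter(nominal, y0 = stats::median(y[cells]),
                        t = t_meas - dt), u[cells[1]], dt, nominal)
        vcells <- valid[cells]
        if (sum(vcells) >= 5)
          blocked[cells] <- detect_runaway(y[cells], y[cells][vcells],
                                           c = qc$runaway_c)
        stp <- pcl_step(y[cells], ctrl[[a]]$fs_shared,
                        .assignment_target(as_, 1), t_meas, nominal,
                        valid = vcells, blocked = blocked[cells],
                        N = N, dt = dt)
        ctrl[[a]]$fs_shared <- stp$filter
        u_next[cells] <- ifelse(valid[cells], stp$stimulus,
                                qc$default_stimulus)
        E_hat[cells] <- stp$posterior$mean[1]
        E_sd[cells] <- sqrt(max(stp$posterior$cov[1, 1], 0))
        F_hat[cells] <- stp$posterior$mean[2]
      } else if (ty == "OL") {
        u_next[cells] <- vapply(seq_along(cells), function(j)
          ctrl[[a]]$ol_seq[[j]][min(i + 1, K)], integer(1))
      }
    }

    out[[i]] <- data.frame(
      cell_id = seq_len(n), interval = i, t = t_meas, y = y,
      F_true = F, E_true = E, H_true = H, length = len,
      stimulus = ifelse(u == 1L, "G", "R"),
      controller = ctype, target = tgt,
      E_hat = E_hat, E_sd = E_sd, F_hat = F_hat,
      S = Sv, P = Pv, valid = valid, blocked = blocked)
    u <- u_next
  }
  log <- do.call(rbind, out)
  rownames(log) <- NULL
  attr(log, "config") <- config
  attr(log, "seed") <- config$seed
  class(log) <- c("experiment_log", "data.frame")
  log
}
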