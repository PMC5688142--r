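# Spectral and phase analysis of single-cell fluorescence trajectories:
# averaged mean-subtracted periodograms, expression-peak detection, and
# period-normalized cross-correlation lags.

#' Average power spectral density of a set of trajectories
#'
#' Computes the raw periodogram of each mean-subtracted trajectory and
#' averages across cells. The normalization satisfies Parseval's relation:
#' the PSD integrated over the one-sided frequency grid equals the series
#' variance (1/n convention).
#'
#' @param trajectories numeric matrix (rows = cells) or list of equal-length
#'   numeric vectors.
#' @param dt sampling interval (min).
#' @return A data.frame with columns `f` (min^-1), `psd` (mean across
#'   cells), `sem` (standard error of the mean across cells).
#' @export
compute_psd <- function(trajectories, dt = 6) {
  if (is.list(trajectories)) {
    lens <- lengths(trajectories)
    if (length(unique(lens)) != 1) stop("trajectories must have equal length")
    trajectories <- do.call(rbind, trajectories)
  }
  trajectories <- as.matrix(trajectories)
  n <- ncol(trajectories)
  if (n < 2) stop("trajectories too short")
  kmax <- floor(n / 2)
  f <- (1:kmax) / (n * dt)
  per <- t(apply(trajectories, 1, function(x) {
    xc <- x - mean(x)
    P <- (dt / n) * Mod(stats::fft(xc))^2
    p <- 2 * P[2:(kmax + 1)]
    if (n %% 2 == 0) p[kmax] <- p[kmax] / 2  # Nyquist bin is not doubled
    p
  }))
  m <- colMeans(per)
  sem <- if (nrow(per) > 1) apply(per, 2, stats::sd) / sqrt(nrow(per)) else
    rep(NA_real_, kmax)
  data.frame(f = f, psd = m, sem = sem)
}

#' Detect expression peaks in a trajectory
#'
#' Smooths the series with a centred moving average, finds local maxima
#' whose prominence exceeds a fraction of the trajectory's range, and
#' refines each peak time by a quadratic fit around the maximum.
#'
#' @param x numeric trajectory (at least 20 points).
#' @param dt sampling interval (min).
#' @param smooth moving-average width (points, default 5).
#' @param prominence minimum prominence as a fraction of the smoothed
#'   trajectory's range (default 0.2).
#' @return Numeric vector of peak times (min, relative to the first sample
#'   at `t = dt`); empty for flat series.
#' @export
detect_expression_peaks <- function(x, dt = 6, smooth = 5,
                                    prominence = 0.2) {
  if (length(x) < 20) stop("series must have at least 20 points")
  n <- length(x)
  sm <- stats::filter(x, rep(1 / smooth, smooth), sides = 2)
  # shrink the window at the edges instead of dropping them
  half <- floor(smooth / 2)
  for (i in which(is.na(sm))) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    sm[i] <- mean(x[lo:hi])
  }
  sm <- as.numeric(sm)
  rng <- diff(range(sm))
  if (rng <= 1e-9 * max(1, max(abs(sm)))) return(numeric(0))  # flat series
  # standard topographic prominence: from each local maximum, scan outward
  # until a strictly higher point (or the edge); the prominence is the drop
  # to the higher of the two intervening minima
  peaks <- numeric(0)
  for (i in 2:(n - 1)) {
    if (!(sm[i] > sm[i - 1] && sm[i] >= sm[i + 1])) next
    l <- i; lmin <- sm[i]
    while (l > 1 && sm[l - 1] <= sm[i]) { l <- l - 1; lmin <- min(lmin, sm[l]) }
    r <- i; rmin <- sm[i]
    while (r < n && sm[r + 1] <= sm[i]) { r <- r + 1; rmin <- min(rmin, sm[r]) }
    prom <- sm[i] - max(lmin, rmin)
    if (prom < prominence * rng) next
    # quadratic refinement around the maximum
    y1 <- sm[i - 1]; y2 <- sm[i]; y3 <- sm[i + 1]
    den <- y1 - 2 * y2 + y3
    off <- if (abs(den) > 1e-12) 0.5 * (y1 - y3) / den else 0
    peaks <- c(peaks, (i + max(-0.5, min(0.5, off))) * dt)
  }
  peaks
}

#' Period-normalized phase lag between two trajectories
#'
#' Finds the lag of the cross-correlation maximum between the
#' mean-subtracted series, wraps it into `(-period/2, period/2]`, and
#' divides by the period, giving a normalized lag in `[-0.5, 0.5]`. Near
#' zero indicates synchrony; +-0.5 anti-phase.
#'
#' @param a,b equal-length numeric trajectories.
#' @param period common oscillation period (min).
#' @param dt sampling interval (min).
#' @return Normalized lag in `[-0.5, 0.5]`.
#' @export
phase_lag <- function(a, b, period, dt = 6) {
  if (length(a) != length(b)) stop("trajectories must have equal length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("phase lag undefined for zero-variance input")
  max_lag <- min(length(a) - 1, ceiling(period / dt))
  cc <- stats::ccf(a - mean(a), b - mean(b), lag.max = max_lag,
                   plot = FALSE, demean = FALSE)
  lag <- cc$lag[which.max(cc$acf)] * dt
  # wrap into (-period/2, period/2]
  lag <- lag - period * round(lag / period)
  if (lag <= -period / 2) lag <- lag + period
  lag / period
}

#' Locate the crossover frequency between two averaged spectra
#'
#' Returns the upper bound of the low-frequency band in which the first
#' spectrum lies below the second: scanning the (lightly smoothed) averaged
#' PSDs from the lowest frequency upward, the crossover is the frequency at
#' which the first spectrum first reaches the second.
#'
#' @param f frequency grid (min^-1).
#' @param psd_a,psd_b averaged PSDs on `f` (a below b at low f).
#' @param smooth moving-average width (bins) applied before comparison.
#' @return Crossover frequency (min^-1); `max(f)` if `psd_a` stays below.
#' @export
psd_crossover <- function(f, psd_a, psd_b, smooth = 3) {
  stopifnot(length(f) == length(psd_a), length(f) == length(psd_b))
  smooth_ma <- function(x) {
    n <- length(x); half <- floor(smooth / 2)
    vapply(seq_len(n), function(i)
      mean(x[max(1, i - half):min(n, i + half)]), numeric(1))
  }
  a <- smooth_ma(psd_a); b <- smooth_ma(psd_b)
  above <- which(a >= b)
  if (length(above) == 0) return(max(f))
  k <- above[1]
  if (k == 1) return(f[1])
  # linear interpolation of the crossing between bins k-1 and k
  d1 <- b[k - 1] - a[k - 1]; d2 <- b[k] - a[k]
  w <- if (d1 - d2 != 0) d1 / (d1 - d2) else 0.5
  f[k - 1] + w * (f[k] - f[k - 1])
}

#' Summarize control errors and perturbation response per controller group
#'
#' For each controller group: the time-averaged absolute error of the
#' population mean to the target, the time-averaged population s.d., and the
#' relative-perturbation statistic used for antibiotic experiments: each
#' cell's mean fluorescence inside the post-perturbation window divided by
#' its group's mean fluorescence inside the reference window immediately
#' before the perturbation.
#'
#' @param log an experiment log (see [run_experiment()]) with columns
#'   `cell_id`, `t`, `y`, `controller`, `target`.
#' @param windows list with numeric 2-vectors `pre` and `post` (min); the
#'   conventional choice is a 5-h interval immediately before the switch and
#'   the interval 10-15 h after it. `NULL` skips the perturbation statistic.
#' @param ma_window moving-average window (intervals) applied to the
#'   population-mean trajectory before the mean-error statistic (default 0:
#'   none). A 1-h window (10 intervals at 6 min) matches the conventional
#'   presentation of population trajectories and separates slow systematic
#'   errors from the fast ripple of binary stimulation, which is common to
#'   all controllers.
#' @return A list with `groups` (data.frame: controller, mean_error,
#'   pop_sd) and, when `windows` is given, `perturbation` (data.frame:
#'   controller, cell_id, relative) plus `quartiles` per controller.
#' @export
summarize_errors <- function(log, windows = NULL, ma_window = 0) {
  if (!is.null(windows)) {
    rng <- range(log$t)
    if (windows$pre[1] < rng[1] - 1e-9 || windows$post[2] > rng[2] + 1e-9)
      stop("analysis windows must lie within the log duration")
  }
  groups <- split(log, log$controller)
  gstats <- do.call(rbind, lapply(names(groups), function(g) {
    gl <- groups[[g]]
    byt <- split(gl, gl$t)
    popmean <- vapply(byt, function(d) mean(d$y), numeric(1))
    tgt <- vapply(byt, function(d) d$target[1], numeric(1))
    if (ma_window > 1) {
      half <- floor(ma_window / 2); nn <- length(popmean)
      popmean <- vapply(seq_len(nn), function(i)
        mean(popmean[max(1, i - half):min(nn, i + half)]), numeric(1))
    }
    mean_err <- mean(abs(popmean - tgt))
    pop_sd <- mean(vapply(byt, function(d) stats::sd(d$y), numeric(1)),
                   na.rm = TRUE)
    data.frame(controller = g, mean_error = mean_err, pop_sd = pop_sd)
  }))
  out <- list(groups = gstats)
  if (!is.null(windows)) {
    pert <- do.call(rbind, lapply(names(groups), function(g) {
      gl <- groups[[g]]
      pre <- gl[gl$t >= windows$pre[1] & gl$t <= windows$pre[2], ]
      post <- gl[gl$t >= windows$post[1] & gl$t <= windows$post[2], ]
      if (nrow(pre) == 0 || nrow(post) == 0) stop("empty analysis window")
      ref <- mean(pre$y)
      cellmeans <- tapply(post$y, post$cell_id, mean)
      data.frame(controller = g,
                 cell_id = as.integer(names(cellmeans)),
                 relative = as.numeric(cellmeans) / ref)
    }))
    out$perturbation <- pert
    out$quartiles <- do.call(rbind, lapply(split(pert, pert$controller),
      function(d) data.frame(controller = d$controller[1],
                             q1 = stats::quantile(d$relative, 0.25),
                             median = stats::median(d$relative),
                             q3 = stats::quantile(d$relative, 0.75))))
    rownames(out$quartiles) <- NULL
  }
  out
}
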