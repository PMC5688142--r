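# Quantification and quality-control rules of the imaging pipeline:
# percentile-based expression extraction from detection regions, growth-rate
# estimation from log2 cell length, the cell classification/invalidation
# state machine, and the pCL runaway-blocking rule.

#' Extract an expression estimate from a detection region
#'
#' Returns the nearest-rank 97th-percentile pixel intensity of the region:
#' the value at rank `ceiling(0.97 * n)` of the ascending sort. For a
#' 40 x 80 box (n = 3200) that is rank 3104, leaving exactly 96 pixels
#' strictly above the extracted value when pixel values are distinct. This
#' convention is robust to cell size, position and segmentation errors.
#'
#' @param region numeric matrix (or vector) of pixel intensities; at least
#'   100 pixels, finite and non-negative.
#' @return Extracted fluorescence (a.u.).
#' @export
extract_fluorescence <- function(region) {
  x <- as.numeric(region)
  if (length(x) == 0) stop("empty detection region")
  if (length(x) < 100) stop("detection region must have at least 100 pixels")
  if (any(!is.finite(x)) || any(x < 0))
    stop("pixel intensities must be finite and non-negative")
  sort(x, partial = ceiling(0.97 * length(x)))[ceiling(0.97 * length(x))]
}

#' Estimate growth rates from a cell-length series
#'
#' Per-step elongation rates are differences in `log2(cell length)` per unit
#' time; steps corresponding to division events (negative jumps of at least
#' 0.5 doublings) and extreme outliers (beyond `k` local MADs from the local
#' median) are excluded, and the remaining rates smoothed with a centred
#' moving average. Windows in which every step was excluded yield the last
#' available estimate (carried forward).
#'
#' @param lengths numeric vector of cell lengths (micrometres) at fixed
#'   intervals.
#' @param dt sampling interval (min).
#' @param window moving-average window (steps, default 5).
#' @param k MAD multiplier for the outlier rule (default 5).
#' @param division_jump threshold (doublings) below which a negative step is
#'   treated as a division (default -0.5).
#' @return Numeric vector of `length(lengths) - 1` growth-rate estimates in
#'   doublings per hour.
#' @export
#' @examples
#' L <- 2 * 2^(seq(0, 4, by = 0.1)) # doubling every 10 samples
#' estimate_growth_rate(L, dt = 6)[1] # 1 doubling / h
estimate_growth_rate <- function(lengths, dt = 6, window = 5, k = 5,
                                 division_jump = -0.5) {
  if (length(lengths) < window + 1)
    stop("need at least window + 1 length points")
  steps <- diff(log2(lengths))                # doublings per step
  rate <- steps / (dt / 60)                   # doublings per hour
  n <- length(rate)
  keep <- steps > division_jump
  half <- floor(window / 2)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    lo <- max(1, i - half); hi <- min(n, i + half)
    loc <- rate[lo:hi][keep[lo:hi]]
    med <- stats::median(loc)
    mad <- stats::mad(loc)
    # noise-free windows have MAD 0; fall back to a 100%-of-median band so
    # gross outliers are still rejected
    thr <- if (mad > 0) k * mad else abs(med) + 1e-9
    if (abs(rate[i] - med) > thr) keep[i] <- FALSE
  }
  out <- numeric(n)
  last <- NA_real_
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    sel <- keep[lo:hi]
    if (any(sel)) last <- mean(rate[lo:hi][sel])
    out[i] <- last
  }
  out
}

#' Classify a cell's validity over an experiment
#'
#' Evaluates the per-interval quality-control flags (continuous presence,
#' growth, constitutive-reporter maintenance, responsiveness of the
#' optogenetic system) and determines the first interval at which any rule
#' fails persistently. Invalidity is absorbing: once a cell is ruled
#' invalid it is eliminated for the remainder of the experiment. For
#' post-hoc analysis the cell's record is truncated to 150 min before the
#' violation to exclude post-failure, pre-invalidation data.
#'
#' @param log a data.frame with one row per interval and (any of the)
#'   columns `t` (min), `present` (logical), `growth` (doublings/h),
#'   `reporter` (constitutive reporter, a.u.), `E_hat`
#'   (controller-estimated responsiveness, a.u.). Missing columns skip the
#'   corresponding rule.
#' @param thresholds list with elements `growth_min` (doublings/h),
#'   `reporter_min` (a.u.), `resp_min` (a.u.); defaults 0.2, 1, 0.1.
#' @param persistence number of consecutive failing intervals required to
#'   invalidate (default 3).
#' @param smooth_window window (intervals) of the moving average applied to
#'   `reporter` before thresholding (default 5).
#' @param truncate_margin post-hoc truncation margin (min, default 150).
#' @return An object of class `validity_record`: list with `flags` (logical
#'   matrix, TRUE = pass), `valid_through` (last valid interval index),
#'   `invalid_from` (interval index or `NA`), `invalid_rule`,
#'   `truncate_at` (min, or `NA`).
#' @export
classify_validity <- function(log,
                              thresholds = list(growth_min = 0.2,
                                                reporter_min = 1,
                                                resp_min = 0.1),
                              persistence = 3, smooth_window = 5,
                              truncate_margin = 150) {
  n <- nrow(log)
  if (n == 0) stop("empty cell log")
  if (is.null(log$t)) stop("log must contain a time column 't'")
  pass <- matrix(TRUE, n, 4,
                 dimnames = list(NULL, c("present", "growing", "reporter_ok",
                                         "responsive")))
  if (!is.null(log$present)) pass[, "present"] <- as.logical(log$present)
  if (!is.null(log$growth))
    pass[, "growing"] <- is.na(log$growth) | log$growth >= thresholds$growth_min
  if (!is.null(log$reporter)) {
    sm <- stats::filter(log$reporter, rep(1 / smooth_window, smooth_window),
                        sides = 2)
    sm[is.na(sm)] <- log$reporter[is.na(sm)]
    pass[, "reporter_ok"] <- sm >= thresholds$reporter_min
  }
  if (!is.null(log$E_hat))
    pass[, "responsive"] <- is.na(log$E_hat) | log$E_hat >= thresholds$resp_min
  fail <- !apply(pass, 1, all)
  invalid_from <- NA_integer_
  invalid_rule <- NA_character_
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (fail[i]) run + 1L else 0L
    if (run >= persistence) {
      invalid_from <- i
      invalid_rule <- colnames(pass)[which(!pass[i, ])[1]]
      break
    }
  }
  truncate_at <- NA_real_
  valid_through <- n
  if (!is.na(invalid_from)) {
    valid_through <- invalid_from - 1L
    truncate_at <- max(0, log$t[invalid_from] - truncate_margin)
  }
  structure(list(flags = pass, valid_through = valid_through,
                 invalid_from = invalid_from, invalid_rule = invalid_rule,
                 truncate_at = truncate_at),
            class = "validity_record")
}

#' Detect runaway cells for pCL blocking
#'
#' Cells that rise to extreme fluorescence before being invalidated would
#' corrupt a population-level feedback signal; they are blocked from the
#' population summary (never from receiving stimuli) when their measurement
#' exceeds `median + c * MAD` of the current valid population. With a
#' degenerate population (MAD ~ 0) an absolute cap of `cap_factor` times
#' the median applies instead.
#'
#' @param y the cell's measurement (a.u.); may be a vector.
#' @param population numeric vector of the valid cells' measurements (at
#'   least 5 for a meaningful summary).
#' @param c MAD multiplier (default 5).
#' @param cap_factor fallback multiplicative cap on the median (default 3).
#' @return Logical vector: blocked flags.
#' @export
detect_runaway <- function(y, population, c = 5, cap_factor = 3) {
  if (length(population) < 5)
    stop("runaway detection needs at least 5 valid cells")
  med <- stats::median(population)
  mad <- stats::mad(population)
  if (mad > 1e-12) y > med + c * mad else y > cap_factor * med
}
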