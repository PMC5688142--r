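# Target fluorescence profiles: constant, step, sine, and raster (rows of a
# binarized image mapped to cells, columns to equal time bins).

#' Construct a target fluorescence profile
#'
#' A `target_profile` maps time (min) to a desired fluorescence level
#' (a.u.). Four kinds are supported:
#' \describe{
#'   \item{constant}{`level` everywhere.}
#'   \item{steps}{piecewise-constant, right-continuous: level `levels[i]`
#'     holds from `times[i]` (inclusive) to `times[i+1]` (exclusive).}
#'   \item{sine}{`mean + amplitude * sin(2 pi (t - phase) / period)`,
#'     floored at 0.}
#'   \item{raster}{one row of a binarized image spread over `duration`
#'     minutes in equal time bins; `TRUE`/1 pixels map to `on_level`,
#'     others to `off_level`.}
#' }
#'
#' @param kind one of `"constant"`, `"steps"`, `"sine"`, `"raster"`.
#' @param level constant level (a.u.).
#' @param levels,times step levels and their start times; `times[1]` is
#'   typically 0.
#' @param mean,amplitude,period,phase sine parameters (a.u., a.u., min, min).
#' @param row logical/0-1 vector: one raster row.
#' @param duration raster duration (min).
#' @param on_level,off_level raster levels (a.u.), default 15 and 0.
#'
#' @return An object of class `target_profile`: a list with a `value(t)`
#'   lookup (vectorized over `t`).
#' @export
#' @examples
#' tp <- make_target_profile("sine", mean = 15, amplitude = 5, period = 480)
#' tp$value(120) # 20 a.u.
make_target_profile <- function(kind = c("constant", "steps", "sine", "raster"),
                                level = 15, levels = NULL, times = NULL,
                                mean = 15, amplitude = 5, period = 480,
                                phase = 0, row = NULL, duration = 1440,
                                on_level = 15, off_level = 0) {
  kind <- match.arg(kind)
  value <- switch(kind,
    constant = {
      if (level < 0) stop("target level must be non-negative")
      local({ lv <- level; function(t) rep(lv, length(t)) })
    },
    steps = {
      if (is.null(levels) || is.null(times) ||
          length(levels) != length(times))
        stop("steps need matching 'levels' and 'times'")
      if (any(levels < 0)) stop("target levels must be non-negative")
      if (is.unsorted(times)) stop("step times must be non-decreasing")
      local({
        lv <- levels; tm <- times
        function(t) {
          idx <- findInterval(t, tm)   # right-continuous: t == boundary -> new level
          idx[idx < 1] <- 1
          lv[idx]
        }
      })
    },
    sine = {
      if (period <= 0) stop("sine period must be positive")
      local({
        m <- mean; a <- amplitude; p <- period; ph <- phase
        function(t) pmax(0, m + a * sin(2 * pi * (t - ph) / p))
      })
    },
    raster = {
      if (is.null(row) || length(row) == 0) stop("raster needs a non-empty row")
      bits <- as.numeric(row) > 0.5
      if (off_level < 0 || on_level < 0) stop("raster levels must be non-negative")
      local({
        b <- bits; dur <- duration; on <- on_level; off <- off_level
        nb <- length(b)
        function(t) {
          idx <- pmin(nb, pmax(1L, floor(t / (dur / nb)) + 1L))
          ifelse(b[idx], on, off)
        }
      })
    })
  structure(list(kind = kind, value = value), class = "target_profile")
}

#' Build one raster target per image row
#'
#' Maps a binarized image (rows = cells, columns = equal time bins) to a
#' list of [make_target_profile()] raster profiles, one per row: the
#' temporal expression pattern each cell should display.
#'
#' @param image logical/0-1 matrix, or a path to a PNG image (binarized at
#'   0.5 after conversion to grayscale; requires the `png` package).
#' @param duration total duration (min) spanned by the columns.
#' @param on_level,off_level fluorescence levels (a.u.).
#' @return A list of `nrow(image)` target profiles.
#' @export
raster_targets <- function(image, duration = 1440, on_level = 15,
                           off_level = 0) {
  if (is.character(image)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG rasters requires the 'png' package")
    arr <- png::readPNG(image)
    if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:min(3, dim(arr)[3])], c(1, 2), mean)
    image <- arr
  }
  image <- as.matrix(image)
  if (length(image) == 0) stop("empty raster image")
  lapply(seq_len(nrow(image)), function(i)
    make_target_profile("raster", row = image[i, ], duration = duration,
                        on_level = on_level, off_level = off_level))
}
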