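# Structured configuration files (YAML or JSON) and log/fixture output.

#' Read an experiment configuration file
#'
#' Parses a YAML or JSON experiment description into an
#' [experiment_config()]. The file mirrors the constructor:
#' ```yaml
#' duration: 960
#' seed: 1
#' population: {n_cells: 30, mean: 1.0, cv: 0.3, seed: 11}
#' assignments:
#'   - {cells: [1,2,3], type: iCL, target: {kind: constant, level: 20}}
#'   - cells: [4,5,6]
#'     type: OL
#'     target: {kind: steps, levels: [10, 20], times: [0, 780]}
#' perturbations:
#'   - {t_switch: 600, gamma_factor: 0.7}
#' ```
#' A hybrid assignment takes `hybrid: {r: 3, d: 0.2, theta: 60, ring:
#' {f: 0.1, mode: transfer}}`; a raster target takes `image: <path.png>`.
#'
#' @param path file path; format chosen by extension (`.json` vs
#'   `.yml`/`.yaml`).
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  else yaml::read_yaml(path)
  if (is.null(raw$duration) || is.null(raw$population) ||
      is.null(raw$assignments))
    stop("config must specify duration, population and assignments")
  ps <- raw$population
  tpl <- cell_params()
  if (!is.null(ps$template)) tpl <- do.call(cell_params, as.list(ps$template))
  pop <- population_spec(ps$n_cells, template = tpl,
                         mean = ps$mean %||% tpl$E_bar,
                         cv = ps$cv %||% 0.3,
                         seed = ps$seed %||% (raw$seed %||% 1L))
  mk_target <- function(tg) {
    if (!is.null(tg$image))
      stop("raster image targets: build with raster_targets() and pass ",
           "'targets' programmatically")
    do.call(make_target_profile, as.list(tg))
  }
  assignments <- lapply(seq_along(raw$assignments), function(i) {
    a <- raw$assignments[[i]]
    out <- list(cells = as.integer(unlist(a$cells)), type = a$type)
    if (!is.null(a$target)) out$target <- mk_target(a$target)
    if (!is.null(a$switch)) out$switch <- list(t = a$switch$t,
                                               type = a$switch$type)
    if (!is.null(a$hybrid)) {
      h <- a$hybrid
      Tm <- NULL
      if (!is.null(h$ring))
        Tm <- ring_transfer_matrix(length(out$cells), h$ring$f %||% 0.1,
                                   h$ring$mode %||% "transfer")
      else if (!is.null(h$T)) Tm <- matrix(unlist(h$T), length(out$cells))
      out$hybrid <- hybrid_params(r = h$r %||% 3, d = h$d %||% 0.2,
                                  theta = h$theta %||% 60, T = Tm)
    }
    out
  })
  experiment_config(duration = raw$duration, population = pop,
                    assignments = assignments,
                    interval = raw$interval %||% 6,
                    perturbations = lapply(raw$perturbations %||% list(),
                      function(e) do.call(perturbation_event, as.list(e))),
                    seed = raw$seed %||% 1L,
                    horizon = raw$horizon %||% 8,
                    qc = raw$qc %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an experiment log to CSV plus JSON metadata
#'
#' @param log an `experiment_log` from [run_experiment()].
#' @param dir output directory (created if needed).
#' @param name base file name.
#' @return Invisibly, the paths written.
#' @export
write_experiment_log <- function(log, dir, name = "experiment") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  meta <- file.path(dir, paste0(name, "_meta.json"))
  utils::write.csv(as.data.frame(log), csv, row.names = FALSE)
  cfg <- attr(log, "config")
  jsonlite::write_json(list(seed = attr(log, "seed"),
                            duration = cfg$duration,
                            interval = cfg$interval,
                            n_cells = cfg$population$n_cells,
                            package_version =
                              as.character(utils::packageVersion("optoloop"))),
                       meta, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv = csv, meta = meta))
}

#' Write a synthetic detection-region image as single-plane TIFF
#'
#' @param region output of [render_detection_region()] (or a numeric
#'   matrix).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_fixture_tiff <- function(region, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF fixtures requires the 'tiff' package")
  img <- if (is.list(region)) region$image else region
  sc <- max(img, 1e-12)
  tiff::writeTIFF(img / sc, path, bits.per.sample = 16L)
  invisible(path)
}
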