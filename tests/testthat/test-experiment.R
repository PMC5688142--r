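# Orchestrator and analysis utilities: determinism, loop-order contract,
# target profiles, spectra, peaks, phase lags, error summaries, config IO.

test_that("target profiles evaluate their closed forms and conventions", {
  sine <- make_target_profile("sine", mean = 15, amplitude = 5, period = 480)
  expect_equal(sine$value(120), 20)
  expect_equal(sine$value(0), 15)
  steps <- make_target_profile("steps", levels = c(10, 20), times = c(0, 780))
  expect_equal(steps$value(779), 10)
  expect_equal(steps$value(780), 20)   # right-continuous at the boundary
  expect_equal(steps$value(c(0, 1000)), c(10, 20))
  expect_error(make_target_profile("constant", level = -1), "non-negative")
  expect_error(make_target_profile("steps", levels = 1, times = c(0, 1)),
               "matching")
  # raster rows map to alternating two-level profiles over equal bins
  img <- matrix(rep(c(0, 1), 12), nrow = 2, ncol = 12, byrow = TRUE)
  tps <- raster_targets(img, duration = 1440)
  expect_length(tps, 2)
  expect_equal(tps[[1]]$value(30), 0)     # first bin (0-120 min) is off
  expect_equal(tps[[1]]$value(130), 15)   # second bin is on at 15 a.u.
  expect_error(raster_targets(matrix(nrow = 0, ncol = 0)), "empty")
})

test_that("experiments replay identically and validate their configs", {
  tgt <- make_target_profile("constant", level = 15)
  cfg <- experiment_config(duration = 120,
                           population = population_spec(4, cv = 0.3, seed = 2),
                           assignments = list(
                             list(cells = 1:2, type = "iCL", target = tgt),
                             list(cells = 3:4, type = "OL", target = tgt)),
                           seed = 5)
  log1 <- run_experiment(cfg)
  log2 <- run_experiment(cfg)
  expect_identical(as.data.frame(log1), as.data.frame(log2))
  expect_equal(nrow(log1), 4 * 20)
  expect_true(all(log1$stimulus %in% c("R", "G")))

  # zero duration: metadata-only empty log
  cfg0 <- experiment_config(duration = 0,
                            population = population_spec(2, seed = 1),
                            assignments = list(
                              list(cells = 1:2, type = "OL", target = tgt)))
  log0 <- run_experiment(cfg0)
  expect_equal(nrow(log0), 0)
  expect_s3_class(log0, "experiment_log")
  expect_identical(attr(log0, "seed"), 1L)

  expect_error(experiment_config(duration = 100,
                                 population = population_spec(2, seed = 1),
                                 assignments = list(
                                   list(cells = 1:2, type = "OL",
                                        target = tgt))),
               "multiple")
  expect_error(experiment_config(duration = 120,
                                 population = population_spec(2, seed = 1),
                                 assignments = list(
                                   list(cells = 1, type = "OL",
                                        target = tgt))),
               "exactly one controller")
  expect_error(experiment_config(duration = 120,
                                 population = population_spec(2, seed = 1),
                                 assignments = list(
                                   list(cells = 1:2, type = "zCL",
                                        target = tgt))),
               "unknown controller")
})

test_that("the logged OL stimuli equal the precomputed broadcast sequence", {
  # the loop-order contract: the stimulus recorded at interval i was applied
  # during interval i, and for OL cells it is exactly the offline sequence
  tgt <- make_target_profile("constant", level = 15)
  cfg <- experiment_config(duration = 240,
                           population = population_spec(2, cv = 0, seed = 3),
                           assignments = list(
                             list(cells = 1:2, type = "OL", target = tgt)),
                           seed = 7)
  log <- run_experiment(cfg)
  nominal <- cfg$population$template
  nominal$E_bar <- cfg$population$mean
  ol <- precompute_ol_sequence(tgt, nominal, duration = 240, N = 8)
  got <- ifelse(log$stimulus[log$cell_id == 1] == "G", 1L, 0L)
  expect_identical(got, ol)
})

test_that("periodograms satisfy Parseval and resolve a pure tone", {
  t <- seq_len(200) * 6
  x <- sin(2 * pi * t / 200)
  ps <- compute_psd(matrix(x, 1), dt = 6)
  expect_equal(ps$f[which.max(ps$psd)], 0.005, tolerance = 0.05)
  set.seed(22)
  xr <- matrix(rnorm(6 * 256), 6)
  ps2 <- compute_psd(xr, dt = 6)
  df <- ps2$f[1]
  v <- apply(xr, 1, function(z) mean((z - mean(z))^2))
  expect_lt(abs(sum(ps2$psd) * df - mean(v)) / mean(v), 0.01)
  expect_error(compute_psd(list(1:5, 1:6)), "equal length")
})

test_that("expression peaks are found, refined, and robust to noise", {
  t <- seq_len(240) * 6
  x <- 10 + 5 * sin(2 * pi * t / 200)
  pk <- detect_expression_peaks(x, dt = 6)
  expect_gt(length(pk), 5)
  expect_equal(median(diff(pk)), 200, tolerance = 6 / 200)
  set.seed(23)
  xn <- x + rnorm(length(x), 0, 0.5)
  expect_equal(length(detect_expression_peaks(xn, dt = 6)), length(pk))
  expect_length(detect_expression_peaks(seq_len(50), dt = 6), 0)  # ramp
  expect_length(detect_expression_peaks(rep(3, 50), dt = 6), 0)   # flat
  expect_error(detect_expression_peaks(1:10), "at least 20")
})

test_that("phase lags recover constructed shifts", {
  t <- seq_len(400) * 6
  a <- sin(2 * pi * t / 240)
  expect_equal(phase_lag(a, a, period = 240), 0)
  b <- sin(2 * pi * (t - 120) / 240)
  expect_equal(abs(phase_lag(a, b, period = 240)), 0.5, tolerance = 0.03)
  cq <- sin(2 * pi * (t - 60) / 240)
  expect_equal(abs(phase_lag(a, cq, period = 240)), 0.25, tolerance = 0.03)
  expect_error(phase_lag(a, rep(1, length(a)), 240), "zero-variance")
})

test_that("error summaries compute the relative-perturbation statistic", {
  # perfect tracking: relative perturbation is exactly 1 for every cell
  t <- rep(seq_len(100) * 6, each = 4)
  log <- data.frame(cell_id = rep(1:4, 100), t = t, y = 15,
                    controller = "iCL", target = 15)
  s <- summarize_errors(log, windows = list(pre = c(60, 300),
                                            post = c(420, 600)))
  expect_equal(s$groups$mean_error, 0)
  expect_equal(s$perturbation$relative, rep(1, 4))
  expect_error(summarize_errors(log, windows = list(pre = c(-10, 5),
                                                    post = c(420, 9000))),
               "within the log duration")
})

test_that("config files round-trip through YAML and JSON", {
  cfgl <- list(duration = 120, seed = 4,
               population = list(n_cells = 3, mean = 1, cv = 0.2, seed = 9),
               assignments = list(
                 list(cells = 1:2, type = "iCL",
                      target = list(kind = "constant", level = 12)),
                 list(cells = 3, type = "OL",
                      target = list(kind = "steps", levels = c(5, 10),
                                    times = c(0, 60)))),
               perturbations = list(list(t_switch = 60, gamma_factor = 0.7)))
  yml <- tempfile(fileext = ".yaml"); jsn <- tempfile(fileext = ".json")
  yaml::write_yaml(cfgl, yml)
  jsonlite::write_json(cfgl, jsn, auto_unbox = TRUE)
  for (path in c(yml, jsn)) {
    cfg <- read_experiment_config(path)
    expect_s3_class(cfg, "experiment_config")
    expect_equal(cfg$duration, 120)
    expect_equal(cfg$population$n_cells, 3L)
    expect_equal(cfg$assignments[[1]]$target$value(0), 12)
    expect_equal(cfg$assignments[[2]]$target$value(70), 10)
    expect_equal(cfg$perturbations[[1]]$gamma_factor, 0.7)
    log <- run_experiment(cfg)
    expect_equal(nrow(log), 3 * 20)
  }
  # logs serialize to CSV + JSON metadata
  dir <- tempfile(); log <- run_experiment(read_experiment_config(yml))
  paths <- write_experiment_log(log, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths["csv"])
  expect_equal(nrow(back), nrow(log))
})

test_that("media perturbation slows growth online by the configured factor", {
  tgt <- make_target_profile("constant", level = 15)
  cfg <- experiment_config(duration = 720,
                           population = population_spec(3, cv = 0, seed = 6),
                           assignments = list(
                             list(cells = 1:3, type = "OL", target = tgt)),
                           perturbations = list(
                             perturbation_event(t_switch = 360,
                                                gamma_factor = 0.7)),
                           seed = 8)
  log <- run_experiment(cfg)
  g_pre <- estimate_growth_rate(log$length[log$cell_id == 1 & log$t <= 360])
  g_post <- estimate_growth_rate(log$length[log$cell_id == 1 & log$t > 420])
  expect_equal(median(g_post, na.rm = TRUE) / median(g_pre, na.rm = TRUE),
               0.7, tolerance = 0.05)
})
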