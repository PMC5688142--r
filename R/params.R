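#' Kinetic parameters of a light-responsive virtual cell
#'
#' Bundles the per-cell kinetic constants of the three-state gene-expression
#' model: promoter activation `H` relaxes toward the applied light input,
#' responsiveness `E` fluctuates as an Ornstein-Uhlenbeck process around the
#' cell's mean responsiveness, and fluorescence `F` integrates production
#' `f0 + k_F * E * H` against first-order dilution at rate `gamma`.
#'
#' Defaults describe a fast-growing *E. coli* cell carrying a CcaSR-type
#' green/red switchable promoter: activation half-time of ~3 min under green
#' light, slower deactivation (half-time ~6 min) under red light --
#' reflecting the slower dark/red reversion of the photoreceptor -- and
#' dilution set by a 25-min doubling time. The production gain is calibrated
#' so the uncoupled hybrid oscillator reproduces trough/peak fluorescence
#' levels near 2 and 11 a.u.; the fully induced steady state
#' `(f0 + k_F * E_bar) / gamma` is then about 60 a.u., so targets in the
#' 10-20 a.u. range used throughout are comfortably reachable.
#'
#' @param k_H promoter activation rate under green light (min^-1).
#' @param k_H_off promoter deactivation rate under red light (min^-1);
#'   deactivation is slower than activation.
#' @param E_bar the cell's mean responsiveness (a.u.).
#' @param tau_E responsiveness relaxation time (min); sets how long
#'   excursions in responsiveness persist.
#' @param sigma_E stationary s.d. of the responsiveness process (a.u.).
#' @param k_F fluorescence production gain (a.u. min^-1 per unit `E` at
#'   `H = 1`).
#' @param f0 leak production rate (a.u. min^-1).
#' @param gamma growth/dilution rate (min^-1).
#' @param omega intensity-per-molecule scale; production/dilution shot noise
#'   has Langevin intensity `omega * (production + dilution)` (a.u.).
#' @param sigma_m measurement noise s.d. (a.u.).
#' @param L0 birth length of the cell (micrometres); division is triggered
#'   near `2 * L0`.
#'
#' @return An object of class `cell_params` (a named list).
#' @export
#' @examples
#' p <- cell_params()
#' (p$f0 + p$k_F * p$E_bar) / p$gamma # fully induced steady state, a.u.
cell_params <- function(k_H = log(2) / 3,
                        k_H_off = log(2) / 6,
                        E_bar = 1,
                        tau_E = 120,
                        sigma_E = 0.2,
                        k_F = 1.66,
                        f0 = 0.02,
                        gamma = log(2) / 25,
                        omega = 0.01,
                        sigma_m = 0.3,
                        L0 = 2.5) {
  stopifnot(k_H > 0, k_H_off > 0, E_bar > 0, tau_E > 0, k_F > 0, gamma > 0,
            L0 > 0, f0 >= 0, sigma_E >= 0, omega >= 0, sigma_m >= 0)
  structure(list(k_H = k_H, k_H_off = k_H_off, E_bar = E_bar, tau_E = tau_E,
                 sigma_E = sigma_E, k_F = k_F, f0 = f0, gamma = gamma,
                 omega = omega, sigma_m = sigma_m, L0 = L0),
            class = "cell_params")
}

# switching rate of H for a given binary input (vectorized over u)
.kH_of <- function(params, u) ifelse(u == 1, params$k_H, params$k_H_off)

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params>\n")
  for (nm in names(x)) cat(sprintf("  %-8s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' State of one simulated mother cell
#'
#' @param H promoter activation in `[0, 1]` (dimensionless).
#' @param E responsiveness (a.u., non-negative).
#' @param F fluorescence (a.u., non-negative).
#' @param length cell length (micrometres).
#' @param t simulation time (min).
#' @param alive logical; dead cells cannot be measured.
#' @param div_thresh current division threshold length (micrometres); drawn
#'   with 5% multiplicative noise around `2 * L0` at each division. If `NULL`
#'   it is set to `2 * length`.
#'
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(H = 0, E = 1, F = 0, length = 2.5, t = 0,
                       alive = TRUE, div_thresh = NULL) {
  stopifnot(H >= 0, H <= 1, E >= 0, F >= 0, length > 0)
  if (is.null(div_thresh)) div_thresh <- 2 * length
  structure(list(H = H, E = E, F = F, length = length, t = t,
                 alive = alive, div_thresh = div_thresh),
            class = "cell_state")
}

#' Specification of a heterogeneous virtual population
#'
#' Cell-to-cell heterogeneity enters through the per-cell mean responsiveness
#' `E_bar`, drawn from a log-normal distribution. The helper arguments
#' `mean`/`cv` parameterize that distribution by its arithmetic mean and
#' coefficient of variation; `cv = 0` gives identical cells.
#'
#' @param n_cells number of mother cells.
#' @param template shared [cell_params()] template.
#' @param mean arithmetic mean of the per-cell `E_bar` distribution
#'   (defaults to the template's `E_bar`).
#' @param cv coefficient of variation of per-cell `E_bar` (default 0.3,
#'   the heterogeneity level used in the population-control experiments).
#' @param seed integer seed making the draw reproducible.
#'
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_cells, template = cell_params(),
                            mean = template$E_bar, cv = 0.3, seed = 1L) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1)
    stop("n_cells must be a positive count")
  if (cv < 0) stop("cv must be non-negative")
  stopifnot(mean > 0)
  structure(list(n_cells = as.integer(n_cells), template = template,
                 mean = mean, cv = cv, seed = as.integer(seed)),
            class = "population_spec")
}

#' A media/antibiotic perturbation event
#'
#' Models a switch to antibiotic-containing media: growth slows by a step
#' factor once the new media reaches the cell (after a transport lag drawn
#' uniformly from `transport_lag_range`), while the expression-side effect is
#' a delayed, exponentially saturating change of the cell's mean
#' responsiveness. The default `gamma_factor = 0.7` reproduces the ~30%
#' growth slowdown observed with sub-inhibitory doxycycline; responsiveness
#' stays at baseline for `resp_delay` minutes after the switch before ramping.
#'
#' @param t_switch time of the media switch (min).
#' @param gamma_factor multiplicative change of the growth/dilution rate.
#' @param resp_factor asymptotic multiplicative change of `E_bar`.
#' @param resp_delay onset delay of the responsiveness ramp (min).
#' @param resp_tau time constant of the responsiveness ramp (min).
#' @param transport_lag_range range (min) of the per-cell media transport
#'   lag, drawn uniformly.
#' @param lag optional fixed per-cell lag (min); if `NULL`, draw one with
#'   [sample_transport_lag()].
#'
#' @return An object of class `perturbation_event`.
#' @export
perturbation_event <- function(t_switch, gamma_factor = 0.7,
                               resp_factor = 1.5, resp_delay = 300,
                               resp_tau = 120,
                               transport_lag_range = c(1, 10),
                               lag = NULL) {
  stopifnot(t_switch >= 0, gamma_factor > 0, resp_factor > 0,
            resp_delay >= 0, resp_tau > 0,
            length(transport_lag_range) == 2L,
            transport_lag_range[1] <= transport_lag_range[2])
  structure(list(t_switch = t_switch, gamma_factor = gamma_factor,
                 resp_factor = resp_factor, resp_delay = resp_delay,
                 resp_tau = resp_tau,
                 transport_lag_range = transport_lag_range, lag = lag),
            class = "perturbation_event")
}

#' Draw per-cell media transport lags for a perturbation event
#'
#' @param event a [perturbation_event()].
#' @param n number of cells.
#' @return Numeric vector of `n` lags (min), uniform on the event's range.
#' @export
sample_transport_lag <- function(event, n = 1L) {
  stats::runif(n, event$transport_lag_range[1], event$transport_lag_range[2])
}
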