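---
title: "Closed-loop optogenetic control of single cells, in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop optogenetic control of single cells, in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoloop)
```

## What this package simulates

Experimental platforms now exist that measure gene expression in hundreds of
individual bacteria trapped in a mother-machine microfluidic device and, every
few minutes, project per-cell red or green light stimuli back onto them to
drive a CcaSR-type optogenetic promoter. Closing this loop in software turns
each bacterium into a plant under model-predictive control, and lets whole
genetic circuits be partly "virtualized": measured fluorescence feeds a
digital model whose state decides the next light input.

`optoloop` reproduces the computational side of such a platform against
simulated cells, so that control strategies, estimator behavior, digital
circuit designs, and the associated quantification rules can be exercised and
tested without hardware. Everything operates on a fixed 6-min
measure-estimate-plan-stimulate cycle.

## The virtual cell

Each mother cell carries three state variables:

* `H(t)` — promoter activation in `[0, 1]`. It relaxes exponentially toward
  the applied binary input `u` (green = 1, red = 0). Activation under green
  light uses rate `k_H = ln2/3` min⁻¹ (half-time 3 min, the minutes-scale
  kinetics of the CcaSR system); deactivation under red light is slower,
  `k_H_off = ln2/6` min⁻¹, reflecting the slower red/dark reversion of the
  photoreceptor. We found a symmetric closure (one rate for both directions)
  incompatible with the slow relaxation oscillations that the hybrid
  circuits must display: with symmetric minutes-scale switching the
  oscillator period is bounded near 70–80 min for any choice of gain,
  whereas the asymmetric closure reproduces both the observed period and the
  observed amplitudes. Given the light history, `H` is deterministic.
* `E(t)` — the cell's transcriptional responsiveness, a latent, time-varying
  gain. It follows an Ornstein–Uhlenbeck process with mean `E_bar`,
  relaxation time `tau_E = 120` min and stationary s.d. `sigma_E = 0.2`
  (reflected at 0). The 2-h correlation time encodes that individual cells
  stay over- or under-responsive for extended periods; no published value
  pins this number, and it is the main free timescale of the model.
* `F(t)` — reporter fluorescence (a.u.). It integrates production
  `f0 + k_F · E · H` against dilution `gamma · F`, with chemical-Langevin
  noise of intensity `omega · (production + dilution)`, i.e. shot noise for
  a birth–death process observed at `omega` intensity units per molecule.

Division is bookkept through an exponentially growing length that halves at
a threshold `2·L0` (5% multiplicative noise); fluorescence is treated as a
per-area concentration and is unaffected by division. Measurements add
truncated Gaussian noise of s.d. `sigma_m`.

Defaults: `gamma = ln2/25` min⁻¹ (fast LB growth), `omega = 0.01` (about
100 molecules per fluorescence unit), `sigma_m = 0.3` a.u. (the percentile
readout is low-noise), `f0 = 0.02` (leak steady state ~0.7 a.u.). The gain
`k_F = 1.66` is calibrated so that the uncoupled hybrid oscillator (below)
reproduces trough/peak fluorescence near 2 and 11 a.u.; the fully induced
steady state is then ~60 a.u., leaving ample headroom for the 10–20 a.u.
control targets. Population heterogeneity enters through per-cell `E_bar`
drawn log-normally; the control experiments use CV 0.3.

Integration uses 0.1-min substeps: the OU step is exact, `H` is analytic,
and `F` uses an exact exponential-decay update of the conditional mean with
the substep-averaged `H`, plus Langevin noise. Halving the substep moves
ensemble moments by well under 1%. A separate validation oracle
(`ssa_oracle`) simulates `F` as a discrete birth–death process in molecule
counts, sampling each frozen-rate substep from the exact transition law
(binomial survival + Poisson immigration), so the Langevin approximation is
checked against an exact sampler.

## Moment equations and the responsiveness filter

Conditional on the light history, `(E, F)` is a linear time-varying
Gaussian system, so prediction means and covariances obey closed moment
ODEs:

$$\dot m = A(t)\,m + c,\qquad \dot V = A V + V A^\top + Q(t)$$

with `A(t) = [[-1/tau_E, 0], [k_F·H(t), -gamma]]`, `c = (E_bar/tau_E, f0)`,
and `Q(t) = diag(2·sigma_E²/tau_E, omega·(f0 + k_F·H·m_E + gamma·m_F))`.
These are integrated with `deSolve::lsoda` at tight tolerance
(`rtol = 1e-9`). Because `H` is known, a standard Kalman measurement update
on the `F` component is exact for this model — the filter weighs prediction
and measurement by their uncertainties, and information about `E` flows
only through the E–F covariance. Negative posterior means are clamped to 0;
the covariance is left untouched. Filters initialize at the population-mean
responsiveness with variance `sigma_E²`, and `F` at the first measurement
with variance `sigma_m²`.

The test suite verifies the filter against an independently constructed
dense joint-Gaussian posterior, checks innovation whiteness, and confirms
calibration (normalized estimation errors of unit variance) on simulated
truth.

## Receding-horizon control and the three controller modes

The planner enumerates all `2^N` binary light sequences over an `N`-interval
horizon (default `N = 8`), propagates the predicted mean fluorescence for
each using the closed-form solution of the mean equations, and picks the
sequence minimizing the summed squared deviation from the target. The cost
is certainty-equivalent — expected levels only, matching a controller that
"minimizes the deviation of the expected fluorescence levels" — with a
predicted-variance penalty available as an option. Ties break toward fewer
green intervals (less photostimulation), then lexicographically red-first,
making planning deterministic.

* **OL** (open loop): the whole sequence is precomputed against the
  deterministic nominal average-cell model, using the planner's own
  predictions as surrogate measurements, then broadcast verbatim.
* **pCL** (population-level closed loop): one shared filter is driven by
  the mean of the valid, non-blocked cells' measurements; one planned
  stimulus is broadcast. We use the mean rather than the median because the
  controller's object is the population mean error, and robustness against
  runaway cells is already provided by a dedicated blocking rule
  (median + 5·MAD); the median remains available.
* **iCL** (individual-level closed loop): each cell has its own filter and
  its own planned sequence.

Mean error (population mean vs target) and individual error (population
spread) separate cleanly across the modes: feedback of any kind removes
mean error, but only per-cell feedback narrows the distribution. When
comparing controllers we compute the mean-error statistic on the 1-h
moving-averaged population trajectory, the conventional presentation, so
that the fast ripple of binary stimulation — shared by all modes — does not
mask the systematic component.

## Hybrid bio-digital circuits

The digital component virtualizes the inhibitory arm of a delayed
negative-feedback oscillator. Per 6-min interval `i`, each cell's virtual
signal accumulates from its measured fluorescence and decays:

$$S_{i+1} = S_i + r\,F_i - d\,S_i$$

and a binary promoter state is `off` when `S > theta` (strictly), driving a
red stimulus, else `on`/green. With `r = 3`, `d = 0.2`, `theta = 60` the
closed loop oscillates indefinitely: expression rises until enough signal
accumulates, the promoter shuts off, fluorescence dilutes away, the signal
decays below threshold, and expression resumes.

Cell–cell communication multiplies the signal vector by a transfer matrix
`T` each interval. Ring topologies are built by `ring_transfer_matrix`:
`transfer` moves a fraction `f` of each cell's signal to each neighbor
(conservative, columns sum to 1), `inhibit` subtracts `f` times each cell's
signal from its neighbors (clamped at 0), and `asymmetric` adds to the left
neighbor while removing from the right. Reading "0.1·S transferred to the
nearest neighbors" as 0.1 to *each* neighbor makes the diagonal 0.8 and
matches the description of 20% of the signal leaving each cell per
interval.

The update order is: transfer, then local production/removal, then
threshold. The placement of the transfer relative to the local update is
consequential and configurable: with the transfer applied *after* the local
update, the diffusively coupled ring is bistable and frequently locks into
an alternating anti-phase pattern; applying the transfer first makes
in-phase synchronization — the behavior seen experimentally for diffusive
coupling — the robust outcome, so that is the default. Inhibitory coupling
on a 4-ring then produces half-period (anti-phase) neighbor lags, and
asymmetric coupling a directed gradient of roughly quarter-period lags.

Circuit groups are simulated with `E_bar` CV 0.1 rather than 0.3: the
experimental oscillator groups are small sets of comparably behaving cells
with similar frequency spectra, and detuning natural periods by ±30% would
put them outside the locking range of the weak `f = 0.1` coupling. Temporal
(OU) variability is kept at full strength and remains the dominant source
of phase diffusion.

## Quantification and quality control

Expression is extracted from a detection region (default 40 × 80 px) as the
nearest-rank 97th-percentile pixel intensity — the value at rank
`ceiling(0.97·n)`, leaving exactly 96 of 3200 pixels strictly above it for
distinct values. The interpolation-free convention reproduces that pixel
bookkeeping exactly. `render_detection_region` generates synthetic regions
whose foreground is calibrated so the extracted value is unbiased for the
true fluorescence.

Growth rates are moving averages of per-step differences in log2 cell
length, excluding division events (negative jumps of ≥0.5 doublings) and
outliers beyond 5 local MADs (with a 100%-of-median fallback when the local
MAD vanishes). Validity classification evaluates presence, growth,
constitutive-reporter maintenance, and responsiveness per interval;
invalidation requires 3 consecutive failing intervals, is absorbing, and
truncates the cell's record to 150 min before the violation for post-hoc
use. Runaway cells (above median + 5·MADs of the current valid population)
are blocked from population-level feedback without affecting their own
stimuli. The persistence count, MAD multipliers and division-jump threshold
are not constrained by the source material and are exposed as parameters.

## Numerical and design choices

* Moment ODEs: `lsoda`, `rtol 1e-9 / atol 1e-11`; planner uses the exact
  closed-form mean propagation (sums of exponentials), so planning is
  integration-free.
* Binary stimuli idealize the platform's brief monochromatic pulses as a
  constant input per 6-min interval; controller state only changes per
  interval, so no within-interval structure is needed.
* Periodograms are raw (no windowing), mean-subtracted per trajectory, and
  normalized so the one-sided spectrum integrates to the series variance;
  averaging across cells gives the population spectrum with its s.e.m.
* Peak detection smooths with a 5-point moving average, uses standard
  topographic prominence with a 20%-of-range threshold, and refines times
  by a local quadratic fit. Phase lags are cross-correlation maxima wrapped
  to `(-period/2, period/2]` and period-normalized.
* Media perturbations draw one transport lag per cell (uniform 1–10 min);
  growth changes step immediately at arrival, while the responsiveness
  effect ramps exponentially after a configurable onset delay, reproducing
  the observed period of stable expression before open-loop divergence.

## Problem sizes

The test suite and the reproduction script use desk-scale versions of the
experiments: ensembles of 10⁴ replicate cells over 30 intervals for
moment-equation validation; 2 × 15 heterogeneous cells over 960–1440 min
for the OL/iCL spectral comparison; 3 × 10 cells over 720 min, 20
replicates, for the controller-taxonomy ranking; 4-cell rings over 40 h and
10 seeds for the coupled-oscillator morphologies. A 30-cell, 960-min
mixed-controller experiment runs in well under a minute on one CPU.

## What the generator does and does not emulate

The virtual cells capture minutes-scale light activation, latent slowly
varying responsiveness with cell-to-cell heterogeneity, expression shot
noise, growth/division bookkeeping, measurement noise, and an
antibiotic-type perturbation (growth slowdown plus delayed responsiveness
shift). They deliberately omit reporter maturation (no delay state —
flagged as an open question in the source material, so it is not guessed;
its absence is visible as a somewhat fast oscillator period), photoreceptor
photochemistry, intermediate light doses, spatial effects inside channels,
real-image segmentation, and any learning of the kinetic constants online.
Passing tests therefore demonstrate correctness of the control, estimation
and circuit machinery under the stated model — not predictive accuracy for
any particular biological strain.
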