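---
title: "Methods: simulating and analysing taste-receptor array recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing taste-receptor array recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(receptomics)
```

# The experiment this package models

A "tongue-on-a-chip" records how an array of reverse-transfected taste
receptor cells responds to transient tastant exposures. Cells carrying a
ratiometric FRET calcium sensor (CFP donor, YFP acceptor) sit in a flow
cell under constant buffer flow; a sample loop injects a plug of tastant
that washes over the array for a controlled time. Each receptor spot yields
a two-channel fluorescence time series; the acceptor/donor ratio rises with
intracellular calcium when a receptor is activated. From these traces the
analysis extracts:

* **iRatio** — the peak ratio increase over the window-start baseline for
  each spot x injection, the basic response statistic;
* **dose–response** parameters (Hill EC50, slope) from an ascending
  injection series, with EC10 as a proposed in vitro taste-threshold
  analog;
* **kinetic metrics** relative to a fluorescein dye injection from the same
  run — onset (peak-maximum delay), fwhm and delta-fwhm "lingering", and
  maximum rise/fall rates — as analogs of sensory time-to-peak and
  lingering;
* **mixed-model contrasts** of log iRatio between injections, reported as
  multiplicative effects with 95% CIs, from which antagonist blocking
  percentages are derived.

No public raw data exist for this kind of experiment, so the package pairs
every analysis stage with a synthetic generator whose defaults encode the
study conditions; all tests and headline numbers run end to end on
generated data.

# Flow-cell exposure model

The loop injection delivers an undiluted plug of duration
$t_{exp} = 60 \, V_{loop} / Q$ seconds ($V_{loop}$ loop volume in uL, $Q$
flow in uL/min). Dispersion in the cell is modelled as a cascade of
`n_tanks` well-mixed compartments (tanks-in-series): the concentration at
the array is the plug convolved with an Erlang kernel whose total mean
residence time is $60 \, V_{cell} / Q$. This is the simplest linear
residence-time model that produces the observed S-shaped wash-in/wash-out
flanks and a saturated plateau; with `n_tanks = 1` it degenerates to an
exponential wash-in, with many tanks it approaches plug flow. An optional
exponential "dead-zone" tail (`tailing_fraction`, `tailing_tau`) slows the
wash-out flank relative to wash-in, matching the observation that the
signal drop is consistently shallower than the rise; it is off by default
and is a generator knob, not a fitted quantity.

Key consequences used as oracles: for any tank count, once the plateau is
reached the fwhm of the simulated peak equals $t_{exp}$ (60 s at
300 uL / 300 uL/min; 30 s at 600 uL/min), and the area under a
single-injection profile equals $t_{exp}$ because the kernel is
normalized. Defaults: `n_tanks = 3`, `dt = 0.5` s (0.1 s for calibration
tables), washout window five mean residence times.

The model deliberately omits Taylor–Aris laminar dispersion and any
loop-volume shortfall (the option `effective_loop_volume` lets a user
reproduce a loop that delivers less than its nominal volume). Spot-position
effects are handled downstream as a per-spot arrival delay, not here.

# Synthetic receptor arrays

`make_array()` lays out replicate spots per receptor type with a uniform
pixel count (default 10–60, so a realistic fraction fails the 15-pixel QC
rule) and a positional arrival delay spread linearly over at most 4 s
across the array. `simulate_traces()` then renders, per spot:

1. **Exposure**: the flow-cell profile shifted by the spot's delay; each
   injection's composition is a named vector of ligand concentrations
   (internally mM).
2. **Occupancy**: per agonist a Hill term
   $c^h / (c^h + (EC_{50}(1 + \sum_I [I]/K_i))^h)$ — competitive
   antagonists shift the effective EC50; multiple agonists add, capped at
   full occupancy. Repeated near-saturating exposures (dose at least 80% of
   the dose giving 95% occupancy) multiply the amplitude by
   `desens_factor` per prior such exposure, emulating receptor
   desensitization.
3. **Calcium kinetics**: the signal tracks occupancy through two parallel
   asymmetric first-order paths sharing an activation rate `k_act` but
   clearing at different rates — a fast path (`k_dec`) and a slow
   "lingering" path (`1/linger_tau`, weight `linger_weight`). We first
   tried the more obvious structure of a bi-exponential release kernel
   plus a rise-rate limiter, but any non-negative convolution kernel ties
   the rise profile to the same exponentials that shape the decay, and it
   provably cannot produce a response that peaks with the exposure yet
   lingers tens of seconds after it — which is exactly the advantame
   phenotype (fast onset, ~39 s lingering). The asymmetric-tracking form
   decouples the two and reproduces all four sweetener kinetic signatures.
4. **Artifacts and channels**: all non-sensor-control spots receive a
   non-specific "dip" proportional to total osmolarity (`dip_gamma` per
   100 mM), mimicking the downward deflection that mock and umami spots
   show under concentrated sucrose; spot-to-spot transfection variability
   is a lognormal amplitude multiplier (`amp_sdlog = 0.25`), which is
   precisely the spot random effect the mixed model later absorbs. Channels
   are rendered as YFP $= B(1 + 0.15 s)$ and CFP $= B(1 - 0.15 s)$ with
   independent 1% multiplicative Gaussian noise on interleaved timestamps
   (YFP lags CFP by half a sampling interval), forcing the downstream
   smoothing/interpolation step. Sensor-control (`YC_CONTROL`) spots carry
   neither signal nor dip.

What the generator does **not** emulate: image segmentation and per-pixel
statistics, gene-dose/transfection chemistry (beyond the amplitude knob),
mechanistic IP3/PLC calcium dynamics, photobleaching and focus drift, and
absolute trace amplitudes (no raw amplitudes are published; only relative
and kinetic quantities are calibrated). Passing tests therefore demonstrate
the correctness and statistical behaviour of the analysis pipeline on data
with this structure, not instrument-level realism.

## Calibrated preset constants

`preset_scenario()` encodes the experiments as self-contained scenarios.
The per-sweetener kinetic constants and the cyclamate inhibition constants
are not free knobs: they were fixed once by grid search/Nelder–Mead
(`tools/calibrate_presets.R`) so that the *noiseless* end-to-end pipeline
reproduces the published kinetic metrics (onset 13 s / lingering 6 s for
100 mM sucrose; 5 s / 39 s for 15 uM advantame; analogously for aspartame
and saccharine) and, over 20 noisy runs, the median blocking percentages
(92/48/33% for TAS2R43/31/8). The calibration objective also penalizes
apparent-EC50 distortion, because a slow activation filter attenuates
narrow low-dose exposure pulses more than saturated ones and the convex
FRET ratio readout amplifies large responses, both of which bias the
peak-readout EC50 upward; the frozen constants keep this bias well inside
the recovery tolerance. After freezing, the constants are treated as part
of the study conditions and are not revisited.

# Trace processing

Channels are smoothed with a centred 3-point moving average, linearly
interpolated onto a common 1 s grid, and divided as acceptor/donor
(YFP/CFP) so that calcium increases give upward peaks. The source
experiments' convention is ambiguous on the ratio order; we fix YFP/CFP
because every published response figure shows upward peaks. QC removes
spots with fewer than 15 pixels (strict) and then receptor groups with
fewer than 5 survivors (strict), in that order; the filter is idempotent
and logs every removal.

iRatio uses a 10 s pre-valve baseline mean rather than the single
window-start sample, for noise robustness, and is floored at zero. The
response window defaults to the exposure duration plus 120 s.

Where a non-responding reference group exists (umami preferred, mock as
fallback), `reference_correct()` subtracts the baseline-anchored reference
excursion from each trace. Subtraction (not division) is used because the
dip superposes additively on the specific signal in the traces. The
correction is exact at the calcium-signal level; because the FRET ratio is
mildly convex in the signal, residual dip leakage after correction is
second-order (<3% of the response at the most concentrated dose) rather
than exactly zero.

# Kinetic metrics

Curves are cut per injection window, smoothed (9-point moving average),
baseline-zeroed, peak-normalized to 100%, and synchronized so the valve
event sits at T = 50 s. The dye reference is the simulated exposure profile
of the fluorescein injection from the same run — fluorescein acts as a
passive tracer of the concentration gradient.

* **fwhm**: time between the first upward and last downward interpolated
  crossing of 50%. Inside `kinetic_metrics()` the width is measured on a
  heavily smoothed copy of the curve, because noise both inflates the raw
  maximum (raising the half-max level) and perturbs the shallow tail
  crossings, either of which narrows the apparent width.
* **Onset** (`peak_max` mode): difference between the times at which the
  response and the reference first attain their maxima. "Attaining the
  maximum" is defined as reaching 95% of a noise-robust plateau estimate
  (the maximum of a heavily smoothed copy): filtered signals approach
  plateaus asymptotically and noise inflates a flat plateau's observed
  maximum, so an exact argmax would degenerate to an arbitrary late point
  of the plateau. This makes the statistic stable under the default 1%
  channel noise; results carry a
  one-grid-step uncertainty, and maxima plateauing wider than 25% of the
  fwhm trigger a broad-maximum warning (long exposures make onset
  ill-defined — keep exposures short). An alternative `p90` mode uses the
  first 90%-crossing instead.
* **Lingering**: delta-fwhm of the response over the reference;
  non-positive values are reported as "none". Area-under-curve lingering is
  deliberately not offered: AUC is not comparable across ligands with
  different response amplitudes.
* **Rise/fall rates**: extrema of the central-difference derivative of the
  percent curve, absolute (%/s) and relative to the reference's extrema.

All metrics are invariant to time translation and to positive affine
rescaling of the raw curve, and match closed forms on analytic shapes
(boxcar, triangle, Gaussian) within a grid step; the tests assert all of
this.

# Dose–response fitting

`fit_hill()` fits the four-parameter logistic in log-dose space
(Levenberg–Marquardt, bounded: EC50 within a decade of the dose range,
slope in (0, 10]), on per-spot responses by default so that uncertainty
reflects spot variance. At least four distinct doses and a non-degenerate
response range are required; non-convergence is flagged, never silent.
`ec_fraction(fit, f)` inverts the curve in closed form,
$EC_f = EC_{50} (f/(1-f))^{1/h}$; `f = 0.1` gives the EC10 threshold
analog. No correction is applied for desensitization across the ascending
series (the presets keep all doses below the desensitization threshold);
an injection-order covariate could be added by the user on the iRatio
table if needed.

# Mixed-model contrasts and blocking

Per receptor group, log iRatio is modelled with the injection as fixed
effect and the spot as random intercept (REML). Contrasts between
injections are exponentiated back to the multiplicative scale with 95%
Wald intervals on Satterthwaite degrees of freedom; an effect is
significant when its interval excludes 1. Nonpositive iRatio values are
floored at 1e-4 before the log (count reported); singular fits fall back
to a fixed-effects model with a notice. The interval construction is
validated by a coverage property: across 500 simulated null datasets the
95% interval contains 1 in 95% +/- 3% of fits.

Blocking is quantified from two contrasts against the same blank — agonist
alone ($E_{pure}$) and agonist plus antagonist ($E_{mix}$) — as
$100 (E_{pure} - E_{mix}) / (E_{pure} - 1)$, clipped to [0, 100]. The
reduction is taken on the excess over 1 because a fully blocked receptor
returns to $E = 1$ (no difference from blank), which this formula maps to
a 100% block; a reduction of the raw estimates would not.

# Problem sizes and runtime choices

The shipped presets use the published replication levels (11–15 sweet
spots; 14 spots per bitter receptor before QC), 1% channel noise, 0.2 s
simulation grids, 2 s channel sampling and 1 s analysis grids. Stochastic
recovery checks use medians over 20 seeded runs, and the null-coverage
property uses 500 single-contrast datasets; these sizes give stable
medians and binomially tight coverage estimates while keeping the full
test suite and the acceptance script fast on a single CPU.

# Known limitations

* The generator's kinetics are phenomenological; parameters are calibrated
  to reproduce published summary metrics, not fitted to raw traces.
* Absolute iRatio scales, and hence contrast magnitudes against blank
  injections, depend on the noise floor of the blank windows; only
  relative quantities (blocking percentages, significance patterns) are
  calibrated.
* Onset on long exposures is intrinsically ill-defined (broad maxima); the
  attainment band mitigates but cannot remove this — the package warns
  instead.
* The mixed model assumes log-normal iRatio with a common residual
  variance across injections; blank windows are noise-floor-dominated and
  mildly violate this, which the coverage property bounds in practice.
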