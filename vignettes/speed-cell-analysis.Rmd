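---
title: "Speed-cell analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speed-cell analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speedcells)
```

## The scientific question

Neurons in the hippocampus and medial entorhinal cortex (MEC) carry a
signal about how fast the animal is running. A *speed cell* is a neuron
whose instantaneous firing rate is significantly correlated with running
speed; the correlation may be positive (p-Speed) or negative (n-Speed),
and the rate may lead the speed (prospective coding) or follow it
(retrospective coding). This package implements the full single-unit
analysis chain needed to measure these properties from extracellular
recordings — spike times, two-LED video tracking and LFP — and to classify
cells physiologically, together with a synthetic-session generator so that
every stage can be validated by parameter recovery.

## The analysis model

### Kinematics

Tracking (30 Hz, front/rear head-mounted LEDs) is linearly interpolated
into 25.6-ms bins and the position is smoothed by local regression with
tricube-weighted linear least squares over an 11-bin (281.6 ms) window —
the fixed-width "lowess" smoother. Instantaneous speed is the per-bin
displacement divided by the bin width, smoothed with a Gaussian kernel of
SD 512 ms (configurable among 128/256/512/1024 ms for filter-size
sensitivity analyses). Only *walking* bins, 2–50 cm/s inclusive, enter any
speed statistic; the bounds are configurable. Bins inside tracking gaps
longer than 1 s are masked.

Two placement details matter for lag estimation and were chosen to keep
the speed estimate *centred*: the bin-to-bin displacement is attributed to
the midpoint between the two bins (averaging the two adjacent steps),
not to the left bin. An uncentred estimator shifts every temporal-lag
estimate by half a bin, which is visible at the one-bin accuracy this
analysis targets.

### Speed score, shuffle null and classification

The speed score is the Pearson correlation between the Gaussian-smoothed
instantaneous rate (spike counts per 25.6-ms bin over bin width, same
kernel as speed) and the smoothed speed over walking bins. Significance
comes from a circular-shuffle null: each of 100 surrogates time-shifts the
spike train by a uniform draw from [30 s, T − 30 s], wrapping the end of
the session to the beginning, and re-runs the *full* rate pipeline —
binning and smoothing are repeated per surrogate so the surrogate scores
carry the same autocorrelation structure as the observed one. Nulls are
pooled across all cells and cells are classified by strict comparison with
the pooled 1st/99th percentiles (a per-cell mode is available). Zero
variance in either series yields a flagged undefined score, never 0.

### Slopes, information, temporal shift

The speed slope is the OLS slope of rate on speed (Hz per cm/s); the
normalised slope divides the rate by its mean first (s/cm). Speed
information uses the Skaggs formulation on a tuning curve of 4-cm/s bins
spanning 2–50 cm/s:

- per spike: `sum_i p_i (lambda_i/lambda) log2(lambda_i/lambda)`
- per second: `sum_i p_i lambda_i log2(lambda_i/lambda)`

with `0·log 0 := 0`; the identity `per_sec = lambda · per_spike` holds
exactly and is asserted on every unit. Zero-occupancy speed bins are
excluded before `p_i` is renormalised.

The temporal-shift curve correlates rate at time `t` with speed at
`t + tau` for `tau` in −1536…+1536 ms in 25.6-ms steps. **Sign
convention:** positive `tau` means the rate is compared with *future*
speed, so a positive preferred shift (the argmax of the curve) is
prospective coding and a negative one retrospective. The zero-lag entry is
the speed score bit-for-bit (shared code path). Cells whose argmax falls
on either end of the window are flagged and excluded from shift summaries.
Within the shift analysis the speed mask is evaluated at the speed
timestamp and rate bins shifted off the session edge are dropped; no
wraparound (wraparound belongs to the shuffle null only).

When recovering the generator's speed gain for a *lagged* unit, the slope
at zero lag is attenuated by the speed autocorrelation at the true lag;
`speed_slope(rate, speed, lag = tau_hat)` evaluates the regression at the
recovered preferred shift, which removes that attenuation. The
conventional (zero-lag) slope remains the default and is what the
per-unit tables report.

### Theta analysis

Theta epochs are detected automatically from the ratio of 5–11 Hz power
to the power in the flanking 1–4 Hz and 12–14 Hz bands, in 2-s windows
stepped by 1 s; windows with ratio above 2 are merged and epochs shorter
than 1 s dropped. The published workflow adjusted epochs manually after
the same ratio criterion; the threshold here is a configurable stand-in
for that step, which is why accession-scale epoch counts can differ by a
few percent. With a ~5% single-window false-trigger probability against
*white* noise at threshold 2, the automatic detector is intended for real
LFP whose non-theta spectrum is 1/f-dominated (high delta power), where
false triggers are rare.

Spike phases come from the Hilbert transform of the 5–11 Hz zero-phase
band-passed trace: the unwrapped instantaneous phase is interpolated
linearly at spike times and wrapped modulo 2π. The convention is peaks = 0
and 2π, troughs = π; phase is invariant to LFP amplitude scaling. Only
spikes inside theta epochs and walking bins are used. The preferred phase
and resultant length `R` are the circular first moment. The theta index is
(mean autocorrelogram count at 100–140 ms − mean at 50–70 ms) / (their
sum) on 5-ms bins; cells with index > 0.2 are theta-modulated. The
autocorrelogram uses raw coincidence counts — the index is scale-free, so
rate normalisation is irrelevant.

### Spatial and directional coding

Rate maps use 3-cm bins with occupancy and spike-count maps smoothed
separately (Gaussian SD 3 cm) before division; only periods faster than
2 cm/s contribute. The spatial autocorrelogram evaluates, per lag, the
Pearson correlation with edge correction over bins defined in both shifted
copies, undefined where fewer than 20 bins overlap. The gridness score
finds the central peak radius (first local minimum of correlation vs
distance, or first crossing below 0.2, whichever comes first), then scores
expanding annuli by `min(r60, r120) − max(r30, r90, r150)` where `r_a` is
the correlation of the annulus with its rotation by `a` degrees (bilinear
interpolation about the centre; undefined bins excluded pairwise); the
score is the maximum over annuli. The published procedure names a 2.5-cm
annulus step while its maps use 3-cm bins; one map bin (3 cm) is used here
and the step is configurable. Head-direction tuning uses 6° bins with time
(dwell) occupancy, no smoothing, and the shared information formulas.

### Cell-type classification

Monosynaptic connections are detected by the jitter test: each spike of
both trains is jittered uniformly on ±5 ms, 1000 times; global 99% bands
are the 99th/1st percentiles of each surrogate cross-correlogram's
maximum/minimum over ±20 ms; a verdict requires a crossing at latency
1–5 ms (the 0–1 ms bin is ignored for same-electrode pairs). These
jitter-identified units seed a linear discriminant on waveform
trough-to-peak latency and asymmetry index that labels the remaining
population; with too few labelled units a fixed boundary is used.

Hippocampal interneurons are typed from their 1-ms autocorrelogram: the
burst index is (peak in 0–10 ms − mean in 40–50 ms) / max(peak, baseline)
(range [−1, 1]); the refractory period is the first bin whose
instantaneous ACG derivative, taken from 0 to the global ACG peak,
exceeds one SD of those derivatives. PV: positive burst index and
refractory < 7 ms; SOM: negative burst index and refractory > 4 ms;
anything else unclassified. Two readings of "the peak measured between 0
and 10 ms" exist — the maximum bin (used here, the natural reading for
sharp burst peaks) or the window mean; with the maximum, near-flat
autocorrelograms acquire a small positive bias of order `1.5/sqrt(m)` for
per-bin counts `m`, negligible at interneuron firing rates.

EC2 principal cells are split into putative pyramidal and stellate cells
by decision regions in (preferred phase, resultant length) polar space
relative to local EC2 theta. The authoritative region parameters were
published only as external calbindin-calibrated code that is not shipped
here; `ec2_default_regions()` is an explicitly labelled placeholder
(strongly trough-locked → pyramidal), and any real inference must supply
the published regions via the `regions` argument.

## The synthetic-session generator

The generator is the package's verification instrument. It emulates:

- **Trajectory**: speed is an Ornstein–Uhlenbeck process reflected at
  zero (mean 15 cm/s, relaxation 0.5 /s, diffusion 8 cm·s^−3/2), chosen so
  roughly 90% of time falls in the 2–50 cm/s walking band, matching the
  0–50 cm/s range typical of open-field foraging; heading is a smoothed
  random walk reflected at the walls of a 120- or 180-cm arena; the rear
  LED trails the front by 12 cm along the heading (midline-mounted LEDs
  10–15 cm apart).
- **LFP**: an 8-Hz carrier (optionally speed-modulated in frequency) plus
  Gaussian noise at 1250 Hz, peaks positive so the phase convention is
  testable by construction.
- **Spike trains**: inhomogeneous point processes with intensity
  `lambda(t) = max(0, baseline + b·v(t + Delta)) · g_theta(phi(t)) · g_space(x(t))`,
  where `g_theta` is a von Mises gain normalised to unit mean and
  `g_space` an optional place/grid/head-direction gain. Note the sign:
  positive `Delta` couples the rate to *future* speed, i.e. prospective
  coding, matching the sign convention of the shift analysis. Spikes are
  drawn by exact thinning of a homogeneous process at the 1-ms-grid
  intensity maximum; burst doublets are appended with a configurable
  probability and intra-burst interval, and an absolute refractory period
  is enforced last. Each unit has its own RNG stream derived from (master
  seed, unit index), so adding units never perturbs existing ones.

What it does **not** emulate: tracking noise and LED occlusions (dropouts
must be injected explicitly), non-stationary behavioural states, theta
frequency/amplitude modulation by behaviour beyond the optional linear
term, phase precession, relative refractoriness or adaptation, and
correlated noise across units. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated statistical
model, not robustness to every artefact of real recordings.

## Problem sizes and numerical choices

The validation suite uses 20-minute single-trajectory sessions for
parameter recovery (30 units over speed gains 0.1–0.5 Hz/(cm/s) and lags
±512 ms), 300-s sessions with 500 unmodulated units for the 1%-tail
calibration of the shuffle classifier, and 300-s spike trains for the
jitter-test calibration (100 planted-connection runs, 500 independent
pairs). These sizes give the estimators enough data to meet their stated
accuracies (median slope error below 10%, median shift error within one
25.6-ms bin, binomial-interval tail calibration) while keeping a full run
in the minutes range.

Numerical details worth knowing:

- Gaussian kernels are truncated at ±4 SD and renormalised over the
  available valid bins, so constants are preserved at series edges and
  around masked bins; the kernel transform is memoised because the
  shuffle null re-applies it hundreds of times per cell.
- The walking band is inclusive, `[2, 50]` cm/s; the mask is applied
  after smoothing (smooth-then-mask, configurable in principle, since the
  published order is unstated).
- Percentile thresholds use strict inequalities; ties sit with non-speed.
- Degenerate inputs (constant rate, zero occupancy, too few spikes)
  produce flagged `NA` results with a reason in the session exclusion
  log, never silent zeros.
- The lowess interior window reduces to a fixed FIR filter (a symmetric
  weighted mean), with truncated weighted least-squares fits at the first
  and last half-windows; a linear ramp passes through unchanged, which is
  the property that makes the speed estimate locally unbiased.

## Known limitations

- The theta-epoch detector replaces a manual curation step; its threshold
  is honest but not equivalent to expert adjustment.
- The EC2 pyramidal/stellate boundary is a placeholder (above).
- The jitter-based E/I template transfers to a waveform hyperplane; with
  few connected pairs (sparse recordings) the fixed fallback boundary
  carries more weight and should be calibrated per preparation.
- Grid tuning in the generator is an imposed rate map, not attractor
  dynamics; gridness validation uses analytic hexagonal constructions.
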