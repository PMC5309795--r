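---
title: "Methods: directed oscillatory coupling between amygdala and hippocampus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directed oscillatory coupling between amygdala and hippocampus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lfpcoupling)
```

## The scientific question

When humans attend to motivationally salient stimuli (dynamic fearful faces
versus neutral landscapes), intracranial recordings show that the amygdala
and hippocampus both respond with high-gamma (HG, 70–180 Hz) activation — a
proxy for local population spiking — and that the two structures synchronise
in the theta/alpha range. The substantive claim this package operationalises
is *directional*: amygdala low-frequency phase entrains hippocampal gamma
amplitude, and not the reverse. Because clinical recordings of this kind are
not publicly deposited, the package pairs every estimator with a synthetic
LFP generator whose coupling structure is known exactly, so each stage of
the chain can be validated by parameter recovery rather than by eyeballing.

## The synthetic session

`make_task_schedule()` reproduces the block/clip design: 9 neutral blocks
alternating with 8 aversive blocks of 24 s each, tiled contiguously by
70 + 71 movie clips whose durations are drawn from a truncated normal
(2.8 ± 1.3 s) and rescaled so each block is filled without gaps, preceded by
a 0.5 s blank used as the session baseline. Whether the session opens with a
neutral or an aversive block is not constrained by the design; the generator
defaults to neutral-first and exposes `first_condition`.

`simulate_lfp()` builds each channel from four ingredients:

* **1/f background** — white Gaussian noise shaped in the frequency domain
  with amplitude ∝ f^(−χ/2) (default χ = 2), normalised to unit variance.
  Frequency-domain shaping was chosen over AR approximations because it
  gives an exactly controllable exponent.
* **Low-frequency oscillation** — Gaussian narrow-band noise (2 Hz spectral
  width) centred at 6 Hz (amygdala) or 6.5 Hz (hippocampus), amplitude 2.
  A stochastic oscillator, rather than a sinusoid, is essential: two pure
  sinusoids at the same frequency have a constant phase difference and would
  make any PLV trivially 1. The 2 Hz width makes the phase decorrelate
  across seconds, so 1 s PLV windows are close to exchangeable units.
* **Cross-frequency coupling** — the receiver's gamma carrier (narrow-band
  noise at 100 Hz) has instantaneous amplitude
  `base + depth · (1 + cos φ_driver(t − lag)) / 2`, where `φ_driver` is the
  driver's low-frequency Hilbert phase and the lag defaults to 15 ms
  (driver leads). `depth` is 0.6 in aversive blocks, 0.2 in neutral blocks,
  and 0 in the blank.
* **Phase–phase coupling** — the receiver's theta is a mixture
  `sqrt(1−b²)·own + b·driver(t − lag)` with b = 0.8 (aversive) / 0.5
  (neutral). This parameter is not strictly needed for PAC but is what makes
  inter-regional PLV and raw-signal Granger causality carry signal; the
  values were fixed once so that, by construction, within-condition PLV
  exceeds its permutation null in *both* conditions while the aversive
  condition is clearly stronger — the qualitative pattern the analyses are
  meant to detect.

Clip onsets add an evoked HG transient (half-cosine rise of 100 ms, 300 ms
plateau, 300 ms fall) whose onset latency is region-specific (120 ms
amygdala, 240 ms hippocampus) and whose amplitude is condition-dependent
(0.6 aversive, 0.15 neutral). An optional 60 Hz component plus harmonics is
added *identically* to every contact, so white-matter re-referencing can
cancel it. Everything is deterministic given the seed.

What the generator deliberately does **not** emulate: epileptiform
transients, non-stationary background drift, volume-conduction mixtures
beyond the common line component, electrode impedance differences, and any
stimulus-content structure within clips. Passing the recovery suite
therefore shows the estimators are correct and directional under realistic
noise and 1/f background — it does not certify behaviour under every
pathology of clinical data.

## Signal conditioning

Filtering is two-way (forward–backward) linear-phase FIR throughout, with
the filter length tied to the band: `ceil(cycles · fs / low_edge)` samples
with `cycles = 4`. The default tap design is windowed frequency sampling.
A dense-grid least-squares design is available (`method = "ls"`), but at the
cycles-rule length a 4-Hz-wide least-squares band-pass carries 1–3 %
pass-band ripple, which violates the refiltering-idempotence property
(pass-band RMS change < 1 % on refiltering) that the package tests; the
windowed design keeps the centre-gain error below 0.3 % with > 60 dB
stop-band attenuation. For sub-Hz low edges the least-squares system is
ill-sized and the windowed design is used regardless.

Line noise is removed by sliding-window regression: over 10 s segments with
50 % overlap, sine and cosine regressors at 60, 120, 180 Hz are fitted by
least squares and the Hann-weighted fits subtracted (overlap-add). The
segment length is a compromise between tracking mains drift and regressor
conditioning; it is configurable.

Each grey-matter contact is re-referenced to the white-matter contact on its
shaft with the nearest contact index; the mapping is recorded in the channel
metadata. Epoching flags — never drops — trials that leave the recording or
touch a user-supplied bad-interval mask, because artifact review is an
input in this design (manual review in the original workflow), not an
algorithm.

Saccades are detected from the two EOG channels as local maxima of the
per-sample Euclidean gaze velocity above its session-wide 99th percentile,
with a 200 ms refractory rule that keeps the larger peak. The percentile is
computed over the whole session rather than per block — with only ~7 min of
data a per-block percentile would be noisy and would couple the threshold to
the conditions.

## Spectra and the subject-specific band

`welch_psd()` uses 1 s Hamming windows with 50 % overlap. The aperiodic
background is fitted by OLS in two spaces: semi-log (log-power on linear
frequency; slope β) and log-log (slope −χ of the power law P ∝ f^(−χ)).
A power law is linear only in log-log space, so band selection measures
"distance above the fit" in log-power units against the log-log fit; both
fits are always reported so the discrepancy stays visible. The default fit
range is 2–80 Hz and the band search range 4–12 Hz (theta + alpha), with a
4 Hz bandwidth. A candidate peak must rise at least 0.05 log10 units (~12 %)
above the background to count; otherwise the search falls back to the range
midpoint with an explicit flag. The distance criterion makes selection
invariant to overall PSD scaling.

Note one consequence of a strong theta peak: a power-law fit over 2–80 Hz on
a composite channel is biased upward by the oscillatory bump (χ ≈ 2.5 when
the generating exponent is 2). Recovery of the generating exponent is
therefore validated on the background-only white-matter channel; on
oscillatory channels the residual-distance logic, not the absolute slope, is
what the band selection relies on.

The adaptive filter bank steps centre frequencies geometrically by 10 %
(c, 1.1c, …) with half-bandwidth 0.3c, so low-frequency bins are narrow
enough for meaningful phase and high-frequency bins wide enough to contain
modulation sidebands. Each bin is Hilbert-transformed into instantaneous
amplitude and phase (cosine convention: phase 0 at a peak, ±π at a trough).

## Coupling statistics

**PLV** is computed over non-overlapping 1 s windows,
`|mean(exp(i(φ_i − φ_j)))|` per window, aggregated per condition by the
arithmetic mean. Significance is two-step: (1) within each condition, the
pairing of the two channels' windows is shuffled to form a null; a pair must
exceed the 99th percentile in *both* conditions to proceed (this step also
suppresses pairs locked only through evoked responses, which survive window
shuffling differently than ongoing phase locking); (2) window condition
labels are permuted for the difference p-value. Window-level permutation is
used as the exchangeable unit everywhere — never within-window sample
permutation, which would destroy autocorrelation and fabricate significance.

**PAC** is the circular–linear correlation between modulating phase and
modulated amplitude: with r_ca = cor(cos φ, a), r_sa = cor(sin φ, a),
r_cs = cor(sin φ, cos φ),
ρ = sqrt((r_ca² + r_sa² − 2 r_ca r_sa r_cs)/(1 − r_cs²)). Both circular
terms in r_cs come from the *modulating* phase series, per the standard
definition of the circular–linear coefficient. The condition contrast
(z-PAC) Fisher-transforms each condition's ρ, takes the difference, and
standardises it against the window-label permutation null; positive z means
stronger coupling in the first (aversive) condition.

**Lag-PAC** recomputes ρ after shifting the amplitude series in 10 ms steps
over ±200 ms. The sign convention is fixed so that a *negative* peak lag
means the modulating phase precedes the modulated amplitude; a 15 ms
conduction delay therefore peaks at the −10 or −20 ms grid cell.

**PLV difference spectra** (1–30 Hz filter-bank bins, z-normalised across
bins) are smoothed for display with an interpolating spline of order 5;
the spline passes exactly through the bin values, so smoothing never moves
a measured point.

## Directionality

**PSI** uses epoch-averaged complex coherency (single Hann taper per epoch,
zero-padded to the requested resolution δf) and sums
Im(conj(C(f)) · C(f + δf)) over a band of total width 8·δf centred on ν —
centre 8 Hz at δf = 1 Hz spans 4–12 Hz. The "bandwidth" nomenclature is
reconciled as *total* width 8·δf (half-width 4 Hz in that example). Inputs
follow the cross-frequency reading: the modulating channel's band-limited
signal against the modulated channel's HG power envelope. In the pipeline,
δf is tied to the subject band (bandwidth/8 = 0.5 Hz), so the PSI band
coincides with the band in which the coupling was found; realizations are
1 s windows of one condition with 50 % overlap. PSI is antisymmetric by
construction and positive when the first signal leads. A sliding-window
variant (100 ms windows, 25 ms steps) tracks directionality over the epoch
with per-condition 99.5th-percentile trial-shuffle thresholds.

**Spectral Granger causality** low-passes the raw pair at 85 Hz, resamples
to 250 Hz, and fits a bivariate VAR across 1.5 s clip epochs as trial
realizations. The order is chosen by AIC over 1–20 (configurable); all
candidate orders are scored on a common effective sample, because comparing
AICs across different sample counts biases selection upward. Unstable fits
(companion eigenvalues on the unit circle) are refitted at a lower order
with a warning. Geweke's decomposition gives the per-frequency index in both
directions, clipped at zero against floating-point undershoot. Two nulls are
implemented: channel swapping per epoch (within-condition significance
band, 99 % two-sided) and condition-label flipping (aversive − neutral
difference band, two-sided with 1 % tail mass per side — the resolution of
the mixed 99 %/98 % wording in the underlying description).

A small-sample caveat the tests make explicit: when one condition carries a
genuine x→y coupling, the *estimation bias* of the y→x index differs
slightly between conditions, and the label-flip null cannot reproduce a
bias that depends on the true labels. The resulting spurious y→x flags are
in the negative (neutral-greater) direction and orders of magnitude smaller
than the real effect; directional conclusions are therefore read from
positive flagged regions and from the low-frequency mean difference, not
from any flag anywhere.

## Event-locked high gamma

HG amplitude is z-scored within each trial relative to the whole epoch
(removing the positive skew of amplitude values), then shifted by the
session-blank baseline expressed in the same trial's z-units. The first
150 ms of the blank are excluded from that average because the two-way
filter's edge transient inflates amplitude at the very start of the
recording. With only 0.5 s of blank the baseline is a noisy — but
condition-common — constant, so condition *contrasts* are unaffected; the
per-trial pre-stimulus baseline is the documented fallback when no blank
exists.

Condition contrasts use the cluster-mass permutation test: trial labels are
shuffled, the per-timepoint score is the observed (or null) mean difference
standardised by the permutation distribution ("permutation-t"), contiguous
same-sign suprathreshold runs form clusters (two-sided, α = 0.05), and the
corrected p is the fraction of permutations whose maximum |mass| exceeds the
observed cluster's. Onset/offset are the first and last corrected-significant
samples; peak latency is the argmax of the *trial-averaged* aversive trace
within the significant window (earliest sample on ties) — reading "across
all trials" as the average trace rather than a median of per-trial argmaxes,
which is far noisier at these trial counts.

One interaction worth knowing about: on the *receiver* channel, the PAC
modulation itself changes mean gamma amplitude between conditions
tonically, which a clip-locked contrast picks up from t = 0. Evoked-latency
recovery is therefore demonstrated on a non-receiver contact of the same
region, where the evoked transient is the only condition-dependent signal.

Theta-trough-locked maps detect troughs at the phase-wrap points of the
band-limited Hilbert phase (the tolerance below −π scales with the
per-sample phase step so detection is sampling-rate independent), snap each
trough to the filtered-trace minimum within ±2 samples, and average
z-scored-then-squared filter-bank power in 1 s epochs around troughs, with
an optional random-epoch surrogate test.

## Problem sizes used by the validation suite

The test suite runs the full chain on reduced sessions chosen once: most
recovery tests use 4 neutral + 3 aversive blocks of 16 s (36 clips,
~112 s) at 500 Hz, which is the smallest session in which all permutation
statistics remain well-conditioned; the direction-recovery suite uses
4 + 4 blocks of 24 s so the spectral estimators (PSI, Granger) see
study-length blocks; onset-ordering uses the full default schedule because
latency contrasts need the full trial count. Type-I calibration uses 200
replicates at 200 permutations each. These sizes are statements about where
the estimators are expected to work, and the vignette's claims are limited
to what those suites actually compute.

## Known limitations

* The EDF writer targets continuous recordings with integer sampling rates
  and a single record duration; it is an interchange convenience, not a
  general-purpose EDF implementation.
* z-PAC permutes 1 s windows (clips and windows are near-interchangeable in
  a design where clips tile blocks contiguously); clip-level permutation is
  available by passing clip-derived labels.
* The Granger machinery is strictly bivariate; conditional (multivariate)
  extensions are out of scope.
* ICA-based ocular cleanup is treated as an external dependency with a
  remove-and-reproject contract; the package ships the EOG-side controls
  (perisaccadic HG, EOG-PAC) only.
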