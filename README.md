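# lfpcoupling

Directed oscillatory coupling analysis for two-region intracranial field
potentials, written for electrophysiologists who need the full chain from
raw LFP to directional connectivity in one tested package: zero-phase FIR
filtering and line-noise regression, white-matter re-referencing,
subject-specific low-frequency band selection from the 1/f-corrected power
spectrum, event-locked high-gamma statistics with cluster-mass permutation
tests, phase-locking values with a two-step permutation scheme,
circular-linear phase-amplitude coupling with permutation z-scores and
time-lagged profiles, the phase slope index, and spectral Granger
causality. A synthetic-data module generates task-structured sessions with
known coupling parameters so every estimator is validated by parameter
recovery.

## The statistics at the core

For band-limited signals with Hilbert amplitude *a*[n] and phase *φ*[n]:

* **PLV** between electrodes *i*, *j* over 1 s windows:
  PLV = |⟨exp(i(φ_i[n] − φ_j[n]))⟩| ∈ [0, 1].
* **PAC** (circular-linear correlation) between modulating phase φ and
  modulated amplitude a, with r_ca = c(cos φ, a), r_sa = c(sin φ, a),
  r_cs = c(sin φ, cos φ):
  ρ = √((r_ca² + r_sa² − 2 r_ca r_sa r_cs) / (1 − r_cs²)),
  compared across conditions via Fisher's z and a window-label permutation
  null (**z-PAC**), and as a function of time lag (±200 ms in 10 ms steps;
  negative peak lag ⇔ the modulator leads).
* **PSI** from the complex coherency C̃(f):
  Ψ = Im(Σ_f C̃*(f) C̃(f + δf)) over a band of total width 8 δf centred on
  ν (centre 8 Hz, δf = 1 Hz → 4–12 Hz); positive ⇔ the first signal leads.
* **Spectral Granger causality** from a bivariate VAR (AIC order selection)
  fitted across clip epochs at 250 Hz, Geweke decomposition per direction
  and frequency, with channel-swap and condition-flip permutation nulls.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
session (`Rscript analysis/01_simulate.R` … `06_directionality.R`, ~1 min
total). The session is generated with amygdala theta (6 Hz) driving
hippocampal high gamma (100 Hz) at a 15 ms lag, modulation depth 0.6
(aversive blocks) vs 0.2 (neutral), and evoked high-gamma onsets at 120 ms
(amygdala) vs 240 ms (hippocampus). The chain recovers all of it:

```
AMY1  chi = 2.54, band 4.0-8.0 Hz (centre 6.0)
HIP1  chi = 2.52, band 5.0-9.0 Hz (centre 7.0)
background chi (white matter): 2.01

amygdala (AMY1): HG onset 190 ms, peak 486 ms
hippocampus (HIP2): HG onset 304 ms, peak 480 ms
=> amygdala precedes hippocampus, matching the generating latencies

most significant pair: AMY1-HIP1 (diff 0.181, p = 0.004975)
z-PAC amygdala-phase -> hippocampal-HG: 10.92
z-PAC hippocampal-phase -> amygdala-HG: 1.31
lag-PAC peak (forward): -10 ms (negative = amygdala leads)
HG envelope PSD peak (4-12 Hz): 6.0 Hz

PSI amygdala -> hippocampal HG envelope: aversive 0.064, neutral 0.035
direction call: amygdala->hippocampus
```

Reading this: the subject-specific bands land on the generating 6/6.5 Hz
oscillations and the white-matter contact recovers the 1/f exponent χ = 2.
The cluster-test onsets preserve the 120-before-240 ms ordering (onsets are
detection latencies, so they trail the generating latencies). The forward
z-PAC is an order of magnitude above the reverse, the lag profile peaks at
the grid cell adjacent to −15 ms, the gamma envelope itself oscillates at
the driver frequency, and PSI and Granger agree on the
amygdala→hippocampus direction.

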