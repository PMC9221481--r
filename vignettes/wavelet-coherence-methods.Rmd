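---
title: "Methods: wavelet coherence of paired physiological recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet coherence of paired physiological recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavecoh)
```

## The problem

When two people interact muscularly — for example pressing their forearms
against each other isometrically — the mechanical oscillations of their
muscles (measured by mechanomyography, MMG, and mechanotendography, MTG,
near 10 Hz) can synchronize, and the question arises whether their brain
rhythms (EEG) synchronize too, within each person (corticomuscular
coupling) and across the pair (hyperscanning). `wavecoh` implements the
full analysis chain for such paired recordings: signal conditioning,
time-resolved Morlet wavelet coherence with a pointwise surrogate-data
significance test, extraction of significant time–frequency *patches*, the
patch statistics **Sum5PaD** and **WFreq**, and the comparison of *real*
signal pairs (recorded simultaneously in one trial) against *randomly
matched* pairs (assembled across trials), which act as a coincidence null.

Because the kind of paired human data this analysis targets is not publicly
deposited, the package ships a first-class synthetic generator that
reproduces the statistical structure the analysis assumes, so every stage
is testable end-to-end without any download.

## Wavelet coherence

For two signals $s_x$, $s_y$ the package computes the continuous wavelet
transform

$$(W s)(b, a) = \frac{1}{a}\int g^*\!\left(\frac{t - b}{a}\right) s(t)\,dt,
\qquad
g_\sigma(x) = e^{ix}\, e^{-x^2 / 2\sigma^2},$$

with the Morlet mother wavelet, on a logarithmic scale grid mapped to
frequencies $f = 1/(2\pi a)$ spanning 3–30 Hz (12 voices per octave, 41
rows). The coherence is the smoothed, normalized cross-spectrum

$$\mathrm{Coh}(b, a) =
\frac{\left|\langle W_x \overline{W_y}\rangle\right|}
{\sqrt{\langle |W_x|^2\rangle\,\langle |W_y|^2\rangle}} \in [0, 1],$$

where $\langle\cdot\rangle$ is an edge-normalized boxcar running mean along
time whose length is proportional to scale. Its modulus is 1 when the two
signals hold a locally fixed amplitude-and-phase relation over the
smoothing window and falls to a positive null level (not zero — the
estimator is biased upward at small smoothing) for unrelated signals.
Without smoothing the modulus is identically 1; the window length is the
bias/variance knob of the whole method.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `sigma` | 6 | – | Morlet bandwidth; ~2-cycle time resolution near 10 Hz |
| `f_min`, `f_max` | 3, 30 | Hz | analysis borders |
| `voices_per_octave` | 12 | – | density of the scale grid |
| `smoothing_width` | 24 | multiples of scale $a$ | boxcar length $24a \approx 3.8$ cycles |
| `n_surrogates` | 100 | – | surrogate pairs per significance test |
| `alpha` | 0.05 | – | pointwise level |
| `time_decim` | 4 | – | decimation of the map's time grid |

Two of these deserve justification:

* **`smoothing_width = 24`.** The $\sigma = 6$ Morlet has an envelope
  e-folding time of $\sigma a$; a window much shorter than that sees a
  single effective sample, so the coherence estimator degenerates to 1
  everywhere. $24a$ seconds is about two e-folding widths
  ($\approx 3.8$ cycles at every frequency), which gives a broad,
  informative null distribution while keeping the time resolution that
  makes patch durations meaningful.
* **`time_decim = 4`.** The transform is evaluated by FFT filtering. The
  analytic Morlet has no negative-frequency support and decays like a
  Gaussian above its centre frequency, so with $f_{\max} = 30$ Hz and
  $\sigma = 6$ every filter in the bank is (to $<10^{-6}$ of its peak)
  supported below $f_s/4 = 62.5$ Hz. Retaining only the first
  `nfft/4` spectral bins and inverting a 4× smaller FFT therefore yields
  the *exact* transform on a 4×-decimated time grid — a subsampling, not
  an approximation. The map at 62.5 Hz still oversamples the wavelet
  envelope bandwidth (~5 Hz at the 30 Hz row). The factor is reduced
  automatically if a configuration would violate the support condition.

### Pointwise significance

Spurious coherence is separated from genuine coupling with surrogate data:
`n_surrogates` pairs of phase-randomized copies of the two inputs (same
amplitude spectrum, independent uniform phases — single-signal structure
preserved, cross-phase destroyed) are run through the identical coherence
estimator. Per frequency row, the empirical $1-\alpha$ quantile of all
surrogate coherence values (pooled over time and surrogates) is the
threshold, and pixels with `coh > threshold` (strictly) are flagged. The
threshold is per-row because the null level varies strongly with frequency
(narrowband rows have higher spurious coherence). A variance-matched
white-noise null is available behind `surrogate = "white"`. On independent
Gaussian noise the flagged fraction calibrates to $\alpha$; the test suite
checks $0.05 \pm 0.02$ over 200 replicate pairs of 30 s signals, and the
same quantity is what `scripts/acceptance.R` recomputes.

No cone-of-influence masking is applied by default: the map is reported on
the full time–frequency rectangle, and edge pixels are compared against
surrogate values with the same edge geometry.

## Patches, Sum5PaD and WFreq

Significant pixels are grouped into **patches** — 4-connected components of
the significance mask (run-based union-find, oracle-tested against
exhaustive flood fill). Each patch carries its start/end/duration in time,
its frequency extent and range, its pixel count, mean coherence and a
coherence-weighted mean frequency. A pixel's time extent is one grid step,
so single-column patches have positive duration.

* **Sum5PaD (%)** — the summed duration of the five longest patches whose
  frequency extent intersects the band (default 8–15 Hz, where the
  mechanical muscle oscillations live), as a percentage of the whole trial
  duration. Because patches at different frequencies overlap in time the
  value may exceed 100 %. A patch straddling the band edge counts with its
  full duration (clipping to in-band pixels would be an alternative; the
  intersects-band reading is what makes the >100 % behaviour possible).
* **WFreq (Hz)** — the duration-weighted mean of the five longest in-band
  patches' representative frequencies. The representative frequency of a
  patch is its coherence-weighted mean pixel frequency clipped to the band
  (default); the midpoint of the frequency extent is available behind
  `representative = "midpoint"`. With no in-band patch WFreq is undefined
  and returned as `NA`, never as 0.

Ties among the "five longest" are broken by earlier start time, making the
selection deterministic. Fewer than five in-band patches contribute what is
available.

## Signal conditioning

The chain is fixed: trial cut → notch → bandpass → decimation → drift
removal → EEG region averaging, each stage linear and applied zero-phase
(forward–backward), so the zero signal maps to zero end-to-end and region
averaging commutes with the filters.

* **Trial cut.** Task trials are cut to the isometric plateau between
  triggers 2 and 3; maximal-contraction (MVIC) trials whose plateau is
  shorter than 3 s have their start shifted earlier (bounded by trigger 1)
  until 3 s are reached — the minimum the wavelet analysis needs at 3 Hz;
  resting trials with open eyes are used whole.
* **Notch 49–51 Hz.** Order-2 Butterworth band-stop, zero-phase: >20 dB at
  50 Hz, <1 dB one octave away.
* **Bandpass 0.016–256 Hz, 25-tap Hamming FIR.** The stated design mixes
  FIR and IIR vocabulary; the implementation follows the reading that uses
  all printed attributes — a windowed-sinc FIR of width 25 with a Hamming
  window — applied at the original 1 kHz rate (the 256 Hz edge requires
  Nyquist 500 Hz). A 25-tap kernel cannot resolve a 0.016 Hz edge
  (its transition width is ~40 Hz), so the exact DC component is removed by
  mean subtraction before filtering and all sub-hertz content is handled by
  the dedicated drift stage.
* **Decimation 1000 → 250 Hz** behind an order-8 Butterworth anti-alias
  lowpass at 100 Hz (not part of the original description, but mandatory
  engineering before subsampling).
* **Drift removal.** Subtract the order-10 Butterworth lowpass at 1 Hz of
  the signal, pulling it down to oscillate around zero — required to avoid
  leakage in the wavelet estimator. The filter is realised as five
  second-order sections derived from the analog poles: the direct
  transfer-function form of an order-10 lowpass at a normalized cutoff of
  0.008 is numerically fragile. Zero-phase passes use odd-reflection end
  padding with the DC operating point removed, which suppresses startup
  transients (a constant input returns machine-zero output).
* **Region averaging.** The 63 mapped electrodes of a 64-channel 10/20
  montage (reference CPz excluded) are averaged sample-wise into ten
  sub-regions (FM, C, CP, POc, AFle, TLle, POle, AFri, TLri, POri), each
  assigned to one of three statistics regions EEGcen / EEGle / EEGri. The
  map ships as a plain-text table and is user-overridable. Whether the
  original filters were zero-phase is not documented; zero-phase was chosen
  to keep patch time extents alignable across channels.

## Pairing and statistics

A trial contributes 28 signals (force, ACC, 3 MMG-type channels and 10 EEG
sub-regions per subject), i.e. 378 unordered signal pairs. *Real* pairs
come from the same trial; *random* pairs draw their two sides from two
different trials (uniformly under a seed), with durations equalized by
truncation to the shortest trial.

Aggregation to comparison units follows the region-combination layout: per
combination (e.g. `inter-MMGs-EEGcen`) the unit is the sub-region pair;
interpersonal units pool the two symmetric orientations
($X_A\!-\!Y_B$ with $Y_A\!-\!X_B$), intrapersonal units average the two
subjects' copies after averaging trials within each task configuration —
this is the only reading that reproduces the published per-combination
sample sizes (e.g. 6 inter-MMG units, 10 inter-EEGcen units). Force and ACC
keep per-subject units pooled into one group to preserve usable sample
sizes. Task-grouped aggregation (holding vs pushing, HIMA vs PIMA) assigns
each unit by the acting subject's task; for interpersonal combinations the
anchoring side's task is used.

Per region combination the real and random units are compared pairwise:
a Shapiro–Wilk test on the paired differences (p > 0.05) routes to the
paired *t* test with Cohen's $d_z = |MD|/SD_{MD} = |t|/\sqrt{n}$, otherwise
to the Wilcoxon signed-rank test (exact null distribution when tie-free and
small, normal approximation with tie correction otherwise) with effect size
$r = |z|/\sqrt{n}$. Task comparisons across three conditions use a one-way
repeated-measures ANOVA; when Mauchly's test rejects sphericity the
Greenhouse–Geisser $\varepsilon$ rescales both degrees of freedom, and the
effect size is partial $\eta^2 = SS_{cond}/(SS_{cond}+SS_{err})$. All tests
are two-tailed at $\alpha = 0.05$ and deliberately uncorrected for multiple
testing (an explorative design choice); a Benjamini–Hochberg adjustment can
be applied to the output table with `p.adjust` if desired. Coefficients of
variation are $SD/M$ — the definition consistent with the published tables,
whose prose inverts the ratio.

## The synthetic generator

`trial_spec()` / `make_trial_pair()` emulate one coupled trial:

* a **shared drive**: a unit-variance oscillation at `osc_freq_hz`
  (default 10 Hz) whose phase follows a random walk
  (`phase_jitter_sd = 0.05` rad/sample, linewidth well under 1 Hz) with a
  uniformly random initial phase and slow amplitude modulation; with zero
  jitter it collapses to a pure sinusoid (the deterministic calibration
  limit);
* **MMG-like channels** = `coupling × drive + white noise`, with noise at
  6 dB SNR relative to the unit-variance drive (`snr_db["mmg"]`);
* **EEG-like channels** = unit-variance background (1/f spectrum with
  exponent `one_over_f_exp = 1` plus an 8–15 Hz alpha-band rhythm) +
  `coupling × drive`, the coupled component entering at 0 dB relative to
  the background at full coupling (`snr_db["eeg"]`);
* **force/ACC**: drive plus small sensor noise, *identical in both
  subjects' records* — one physical sensor serves both partners;
* triggers at 0 %, 5 % and 95 % of the trial; only the plateau cut between
  triggers 2 and 3 matters downstream.

Defaults (`duration_s = 30`, `fs_hz = 1000`, `coupling = 0.8`) produce
coherence maps with large significant patches around 10 Hz for coupled
pairs and near-null maps for uncoupled ones. The generator reproduces the
*statistical* structure the analysis assumes — narrowband shared drive,
1/f EEG background, common force channel — not the physiology: no fatigue
dynamics, no biomechanics, no EMG, no inter-subject asymmetries. Passing
tests on synthetic data therefore demonstrate that the pipeline recovers
planted coupling structure at realistic SNR, not that any particular
neurophysiological effect exists in real recordings.

In the parameter-recovery check, real-pair inter-MMG Sum5PaD rises strictly
with coupling over {0, 0.3, 0.6, 0.9} (ensemble of 20 seeds, 19 s trials —
the shortest usable trial length, at the 250 Hz analysis rate, 40
surrogates). Random pairs drift upward by a few percentage points at high
coupling — more narrowband energy means slightly more spurious pointwise
coherence, an honest property of the estimator — so "flat" is
operationalised as the random-pair trend being below 10 % of the real-pair
trend (measured ≈ 6 %).

## Numerical choices and degenerate inputs

* Coherence is clipped to $[0,1]$ against rounding; silent channels (zero
  auto-spectrum) yield coherence 0 with a warning rather than NaN.
* Significance uses strict inequality at the threshold, so an all-ties
  degenerate row flags nothing.
* `wfreq` on an empty in-band set returns `NA` (signalled, never 0);
  `sum5pad` on an empty set returns 0 (a length, not a location).
* Paired tests refuse zero-variance differences; the normality gate
  refuses constant input and n < 3; the RM ANOVA reports F = 0, p = 1 for
  identical condition means instead of 0/0.
* All stochastic stages (generator, random pairing, surrogates) consume
  explicit seeds and restore the caller's RNG state; identical
  configurations are bit-identical on rerun.

## Problem sizes used in the checks

The calibration check uses 200 replicate pairs of 30 s white noise at
250 Hz with 100 surrogates each; the recovery sweep uses 4 couplings × 20
seeds × (real + random) at 19 s with 40 surrogates; unit tests run on 3–20 s
signals. These sizes were chosen so the full suite exercises every stage at
the fidelity the statistics require while remaining comfortable to run
routinely on one core.

## Known limitations

* The pointwise test controls the per-pixel error rate, not any area-wise
  or cluster-corrected rate; patch counts on null data are nonzero by
  construction. This mirrors the analysis the package implements; cluster
  correction is out of scope.
* Phase-randomized surrogates preserve each signal's amplitude spectrum
  but destroy *all* phase structure, including any non-Gaussian amplitude
  dynamics; for strongly narrowband signals the null is conservative near
  the drive frequency.
* The smoothing operator is a boxcar in time only; no cross-scale
  smoothing is applied.
* The coherence estimator's upward bias at small effective sample counts
  is not corrected; comparisons are always against surrogates that share
  the bias.
* WFreq's per-patch representative frequency is a modelling choice
  (coherence-weighted mean vs midpoint); both are exposed, and analyses
  relying on WFreq should report which was used.
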