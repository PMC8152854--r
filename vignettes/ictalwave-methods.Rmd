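---
title: "Detection and cross-frequency analysis of electrographic seizures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection and cross-frequency analysis of electrographic seizures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictalwave)
```

## Scope

`ictalwave` implements a complete analysis chain for spontaneous
electrographic seizures in rodent EEG and for epileptiform field
potentials in brain slices: rule-based discharge detection with
low-voltage-fast (LVF) / hypersynchronous (HYP) / incremental onset
classification, a complex Morlet continuous wavelet transform,
phase-amplitude coupling (PAC) via the Kullback-Leibler modulation index,
wavelet phase coherence (WPC) between paired recording sites, and a
Mann-Whitney group comparison of per-subject PAC. A synthetic
local-field-potential generator with exact ground truth drives every
benchmark, so the whole pipeline is testable without animal recordings.

## The discharge model and its detection rules

Spontaneous discharges are modelled as trains of repetitive spikes with
amplitudes about twice the background signal and durations of at least
10 s, terminated by an abrupt spike cessation followed by several seconds
of signal suppression. Detection proceeds on the 2-200 Hz zero-phase
Bessel-filtered trace:

1. **Background level.** "Twice the background signal" is read as twice
   the background's *amplitude*, not its standard deviation: a Gaussian
   background exceeds 2 SD routinely (about 5% of samples), but rarely
   twice its own envelope peaks. The background amplitude is the 95th
   percentile of |x| per 1-s block, tracked through time as the trailing
   0.2-quantile of block values over twice `background_window_s`
   (default 30 s), which keeps the estimate anchored to true background
   even while a discharge occupies most of the trailing window.
2. **Spikes and events.** Suprathreshold runs of
   `|x| > amplitude_factor x background` become spike peaks; peaks closer
   than 120 ms (one biphasic waveform) merge; gaps below
   `spike_gap_tolerance_s` (2 s) join peaks into one event. Edge peaks
   that are both weak (< 60% of the group's median amplitude) and
   isolated (> 0.4 s from their neighbour) are trimmed — they are almost
   always stray background crossings, and keeping them biases onsets by
   seconds.
3. **Duration rule.** Events shorter than `min_duration_s` (10 s) are
   discarded; the duration runs from the LVF onset (when present) to the
   spike cessation.
4. **LVF back-extension.** Before the first spike, sliding 0.4-s windows
   are compared with the SD of the preceding signal; a run of at least
   two consecutive windows at or below 65% that reaches the first spike
   marks an LVF onset of length 0.5-5 s, and the event onset moves to the
   attenuation crossing. The crossing is the reproducible anchor; the
   time of a spike immediately preceding the LVF (when one exists) can be
   read from `first_spike_s`.
5. **Onset classes.** `LVF` when the scan succeeds; otherwise `HYP` when
   the first second already carries the equivalent of at least three
   suprathreshold spikes at near-plateau amplitude — dense clusters can
   merge into one long suprathreshold run, so a run is credited with one
   spike per ~0.3 s of its duration; `INCREMENTAL` when early spikes are
   small (< 55% of the plateau median), i.e. amplitude ramps up from
   baseline; `UNCLASSIFIED` otherwise.

The 2x rule is applied to the filtered envelope rather than the raw
signal — the raw trace carries DC-like shifts that would make the
comparison meaningless — and human adjudication of uncertain events has no
algorithmic counterpart here; the detector's `n_spikes`, `suppressed` and
`lvf_norm_sd_pct` fields serve as its confidence surface.

`quantify_lvf()` reproduces the LVF magnitude measurement: both the LVF
window and the equal-length preceding window are filtered to 2-200 Hz and
the LVF SD is expressed as a percentage of the preceding SD.

## Wavelet transform

The mother wavelet is a complex Morlet with central frequency
`fc = 0.8125` Hz and Gaussian-envelope bandwidth parameter `bw = 5`,

$$\psi(t) = (\pi\,\mathrm{bw})^{-1/2}
  e^{-t^2/\mathrm{bw}}\, e^{j 2\pi f_c t},$$

whose Fourier transform is a unit-peak Gaussian at `fc`. A bandwidth of 5
for a 0.8125 Hz centre looks like an unusually large fractional
bandwidth, but the resulting constant quality factor
$f/\sigma_f \approx 8$ is a sensible eighth-octave resolution at every
analysis frequency; both parameters are exposed in `morlet_params()` for
sensitivity checks. The daughter at analysis frequency `f` is the mother
dilated by `a = fc/f` (the standard scale-frequency convention — the
printed equations leave the mapping implicit). Daughters are
L1-normalised and doubled so that a pure cosine of amplitude A yields
`|W| = A` on its own row; the transform is computed by FFT multiplication
with the one-sided (analytic) frequency response, which equals direct
convolution to machine precision and keeps 60-s traces at 1250 Hz around
a second of work.

Phase is the four-quadrant angle of each coefficient. The printed form
`arctan(Im/Re)` cannot distinguish opposite quadrants and cannot cover
(-pi, pi], so the four-quadrant angle is the only faithful
implementation. Amplitude is the complex modulus. Coefficients within one
envelope e-folding time of either trace edge are flagged by `coi_mask()`.

## Phase-amplitude coupling

Phases are taken on a log-spaced 1-30 Hz grid and amplitudes on a
32-512 Hz grid (4 points per octave by default; the grids hit both band
edges exactly). For each non-overlapping 4-s window — long enough for at
least 4 cycles of every phase frequency at or above 1 Hz; slower rows are
flagged unreliable — the coupling strength of a frequency pair is the
Tort-style modulation index: mean amplitude per 20-degree phase bin,
normalised to a distribution p, and

$$\mathrm{MI} = \frac{1}{\log 18}\sum_k p_k \log (18\, p_k) \in [0,1],$$

the Kullback-Leibler divergence of p from uniform scaled by its maximum.
Empty bins contribute zero; an all-zero amplitude window returns `NA`
with a warning. Windows are non-overlapping because sequential windows
are how the per-event comodulogram panels are organised; overlap is not
offered.

Peri-ictal averaging uses five segments — preictal `[onset-8, onset)`,
onset `[onset, onset+8)`, ictal `[onset+8, term-8)`, offset
`[term-8, term)`, postictal `[term, term+8)` — each 8 s so it holds at
least two 4-s windows. The segment mean is computed per window first
(mean MI over the reliable grid), then across the segment's non-excluded
windows; whether spectral or temporal averaging comes first only matters
when window counts differ across segments, and per-window-first is the
order implemented and tested. Windows containing samples beyond
`artifact_threshold_sd` robust SDs are excluded from all averages. The
default bar is 8 SD for standalone use; the paired pipeline raises it to
15 SD because discharge spikes legitimately reach 8-10 robust SDs, while
the movement artifacts the generator plants (>= 20 SD) still trip it.
The authors' artifact criterion was visual; this one is a stated,
configurable stand-in.

## Wavelet phase coherence

For two aligned traces the phase difference at frequency f is the angle
of the wavelet cross-spectrum,
$\Delta\phi(t,f) = \mathrm{Arg}\,(W_1^*(t,f)\,W_2(t,f))$, and the
coherence over a window of `8/f` seconds (8 cycles) is
$\rho = |\langle e^{j\Delta\phi}\rangle|\in[0,1]$, exactly 1 when the
phase difference is constant — identical traces, or any amplitude-scaled,
constant-phase-shifted copy. The printed denominator of the
$\Delta\phi$ equation (`W1 W2 - W1* W2*`) is a typographical slip — it is
purely imaginary and unrelated to the cross-spectrum — and the
cross-spectrum angle is the form that actually delivers the stated
"one indicates a phase lock" property; this is the documented deviation.

Two summaries are produced. The time-resolved map keeps one rho per
window per frequency (windows tile each frequency independently;
`wpc_matrix()` resamples to a common axis for display). `wpc_collapse()`
additionally grades each frequency across time: every window contributes
one unit phasor at its net phase difference, and the modulus of their
mean is reported. For independent inputs those window phasors are
approximately independent and uniform — window length (about six wavelet
e-folding times) comfortably exceeds the coefficient correlation time —
so the expected collapsed coherence is the classic resultant-length bias
$\sqrt{\pi/(4n)}$ for n windows, which the Monte-Carlo bench reproduces
within its standard error.

## The synthetic generator

The generator produces the statistical structure every detector and
estimator assumes, with exact ground truth:

* **Background**: Gaussian noise spectrally shaped to `1/f^alpha`
  (alpha = 1 by default), rescaled to the target SD exactly. The
  recordings this emulates were digitized at 5000 Hz; benches run at
  500-1250 Hz because every analysis band of interest sits far below
  those Nyquist rates, and `downsample()` covers the path from full-rate
  data.
* **Discharges**: inhomogeneous-Poisson trains of biphasic
  (difference-of-Gaussians) spikes, defaulting to 6 spikes/s at 8
  background SDs — about four times the background amplitude, i.e.
  comfortably past the "approximately 2x" recognition bound, as real
  discharges are. LVF onsets scale the background inside a 0.5-5 s
  window to the requested fraction of the measured preceding SD (exact by
  construction); HYP onsets plant an abrupt 4-spike cluster in the first
  second; incremental onsets ramp rate and amplitude over 5 s.
  Termination is followed by a suppression window at 30% background.
  Amplitudes are expressed in background-SD units throughout the
  generator; physical units enter only at the I/O boundary.
* **Coupling**: slow cosine plus a carrier whose envelope is
  `(1-depth) + depth (1+cos phi)/2`, so depth 0 means no modulation and
  depth 1 means a vanishing envelope at the anti-preferred phase.
* **Coherent pairs**: a shared narrow-band component (band-passed noise)
  weighted by `lock_fraction` against independent 1/f noise.
* **Slice events**: raised-cosine (Hann) bumps for sharp waves
  (20-200 ms) and interictal spikes (200-600 ms; amplitudes in absolute
  mV), and enveloped spike bursts for ictal discharges. Event trains are
  placed on jittered grids with collision guards; ictal extents are
  claimed first and rarer trains before denser ones, so planted
  incidences survive. Ground-truth rows mark rule-violating plants
  (sub-threshold amplitude, out-of-range width or incidence) for the
  detectors' negative tests.
* **Artifacts**: large half-cosine transients in background-SD units,
  with the injection times returned as ground truth.

Every generator is a pure function of its configuration and seed; the
caller's RNG state is restored afterwards.

What the generator deliberately does not model: biophysical network
dynamics, kindling progression, electrode drift, chewing/grooming
artifact morphology, state-dependent background (sleep spindles, theta),
or volume conduction. Passing benches therefore demonstrate that the
estimators recover what they claim from signals with the assumed
structure — not that the rules themselves are optimal for any particular
real recording.

## Field-potential detectors

The slice detectors share one primitive: after subtracting a running
median wide enough that no single event dominates it (slow 1/f drift
would otherwise inflate the noise estimate and shift event baselines),
suprathreshold bumps of the smoothed rectified signal are measured and
their base duration is estimated as twice the full width at half maximum
— exact for the generator's raised-cosine waveforms and stable for any
unimodal bump, unlike a direct low-threshold crossing whose width depends
on amplitude. Sharp waves use a relative threshold (twice the background
amplitude, 1.96 robust SDs); interictal spikes use the absolute 0.5 mV
rule (the trace must be in mV, enforced) after an optional 0.2-500 Hz
Bessel pre-filter; ictal discharges group >= 1 mV spikes into bursts and
classify the trace as ictal-bearing when mean event duration >= 30 s and
mean inter-event interval >= 90 s. Incidence rules (0.3-4 sharp waves/s
over 1-min segments; 2-5 interictal events/10 s) gate each event on the
local incidence in a segment centred on it, clipped at the trace bounds.
`detect_slice_events()` runs the ictal detector first and masks its
extents (plus a 2-s guard) for the brief-event detectors, so burst
spikes are not double-counted.

## Group statistics

Per-subject summarisation precedes group testing — one mean PAC per
segment per subject — to avoid pseudo-replication of events within
animals. The comparison is a two-sided Mann-Whitney U test, exact for
tie-free samples up to 12 per group and a tie-corrected normal
approximation otherwise. At 5 subjects per group the exact test is
discrete: the largest attainable size below 0.05 is 8/252 (about 3.2%),
which is what the null-calibration bench converges to; this is a
property of the exact test, not a miscalibration.

## Numerical choices and problem sizes

* Zero-phase filtering doubles the effective Bessel order; corners are
  pre-warped so the -3 dB points sit at the stated frequencies, and the
  band-pass is a high-pass/low-pass cascade factored into biquads —
  direct transfer-function forms of order 16 are numerically fragile at
  corners three decades below Nyquist.
* FFT lengths are 2-3-5-smooth; awkward prime lengths make R's
  mixed-radix FFT orders of magnitude slower.
* Bench sizes: 50 planted discharges across ten ~500-s traces at 500 Hz;
  60-s coupling recovery at 1250 Hz; 20 seeds x 5 depths for
  monotonicity; 200 Monte-Carlo replicates for the coherence null; 200
  simulated studies for test calibration; a 450-s slice trace at
  1000 Hz. These sizes keep each bench between seconds and a few minutes
  on one CPU while leaving the pass margins wide.
* Tie-breaks: events separated by less than the spike-gap tolerance
  merge; equal-amplitude comodulogram maxima resolve to the first grid
  index (only relevant on degenerate inputs).

## Known limitations

* Incremental onsets whose ramp starts below the detection threshold are
  anchored at the first suprathreshold spike, so their onset lags the
  generative ramp start and the class is frequently read as HYP; the
  LVF/HYP distinction — the one the downstream analyses rely on — is the
  benched quantity (>= 90% agreement).
* LVF recovery from a single short window inherits the sampling noise of
  an SD ratio over a few hundred effective samples; the bench asserts
  the median relative error (<= 20%), and individual short-window events
  can exceed it.
* The EDF writer covers the subset this package needs (continuous
  recording, equal rates, single data record); it is not a general EDF+
  implementation.
* WPC window tiling starts at the trace origin per frequency; a window
  straddling an event boundary dilutes coherence at the slowest
  frequencies, where windows are tens of seconds long.
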