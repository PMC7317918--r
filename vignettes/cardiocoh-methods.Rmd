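---
title: "Wavelet phase coherence of cardiorespiratory dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet phase coherence of cardiorespiratory dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cardiocoh` quantifies the coupling between heart rate and respiration — and
its association with periodic breathing (PB) under hypoxia — from
simultaneously recorded physiological time series. This vignette explains
the model underlying each stage, the tunable parameters and their defaults,
what the synthetic cohort generator does and does not emulate, and the
numerical choices a maintainer would want recorded.

## The analysis model

### Time-frequency representation

Physiological oscillations (cardiac ~1 Hz, respiratory ~0.25-0.35 Hz,
vasomotion down to 0.005 Hz) drift in frequency, so spectra are computed
with a continuous wavelet transform on a logarithmic frequency grid rather
than a Fourier transform. `cwt_tfr()` convolves the signal with an analytic
wavelet at each scale via frequency-domain multiplication. Two wavelets are
available:

* **lognormal** (default): a Gaussian window in log-frequency,
  `exp(-(2*pi*f0)^2/2 * ln(f/fc)^2)`, zero for non-positive frequencies;
* **Morlet**: a Gaussian in linear frequency centred on the scale frequency.

The resolution parameter `f0` (default 1) sets the time-frequency
trade-off; at `f0 = 1` the lognormal window has a log-frequency SD of
`1/(2*pi)`, i.e. about a quarter octave. The grid uses 32 voices per octave
(2.2% spacing) over 0.005-2 Hz by default, so "within one grid step"
statements are meaningful at the precision of the reported frequencies.

Coefficients are amplitude-normalised: a unit sinusoid at a grid frequency
yields `|W| = 1` on its row away from edges. This makes ridge amplitudes
directly interpretable and leaves phase-based statistics unaffected. A
consequence worth knowing: the time-averaged power of white noise grows
proportionally to frequency (each window captures a bandwidth proportional
to its centre frequency); under an energy normalisation the same spectrum
would fall as `1/f`. The package's tests assert the flat power-per-octave
form, which is the normalisation-independent content of that statement.

**Preprocessing.** Before transforming, a cubic polynomial trend is
subtracted and the signal is band-limited to the transform range by zeroing
Fourier components outside it. This removes non-oscillatory drift that
would otherwise dominate the lowest octaves.

**Edges.** Each row's cone of influence (COI) is set to twice the e-folding
time of the wavelet envelope at that frequency, and COI coefficients are
excluded from every time average. The factor of two is deliberate: the
lognormal wavelet's envelope has slow time tails, and at exactly one
e-folding time the retained amplitude is still biased by about 8%, whereas
at twice that distance the bias is around 0.1%, consistent with the
package's 1% amplitude-stability contract.

**FFT padding.** Transforms are zero-padded to the next 5-smooth length
(factors 2, 3, 5) that also covers the wavelet tail at the lowest analysed
frequency. Padding beyond the envelope support makes the circular
convolution equivalent to a linear one; 5-smooth lengths keep R's
mixed-radix FFT fast without changing any retained coefficient.

### Instantaneous rates

`extract_ridge()` traces one oscillatory mode through a band of the
transform: a dynamic-programming (Viterbi) path that maximises summed
(max-normalised) coefficient amplitude minus a quadratic jump penalty
`lambda * (delta log2 f)^2` between consecutive samples, with `lambda = 2`
per octave squared. The path is refined by quadratic interpolation in
log-frequency across the three rows around it; the phase is the argument of
the on-path coefficient. The instantaneous heart rate (IHR) is extracted in
0.5-2 Hz, the respiration rate in 0.145-0.6 Hz, and the resulting rate
series are resampled to the 40 Hz working rate.

ECG needs one extra step. A pulse-train ECG is a comb of near-equal
spectral lines (fundamental and harmonics), so a purely amplitude-maximal
path can lock onto the second harmonic. `ihr_from_ecg()` therefore first
locates the cardiac fundamental — the lowest local maximum of time-averaged
amplitude reaching half the band maximum — and extracts the ridge within
half an octave of it, which excludes the first harmonic at physiological
rates. This is an initialisation of the ridge scheme, not harmonic
tracking.

Two estimator caveats are verified by tests rather than assumed: the ridge
rate agrees with the beat-to-beat (R-R inversion) rate to within 0.02 Hz on
average at moderate respiratory sinus arrhythmia, but the wavelet ridge
low-passes beat-to-beat variability, so the pointwise difference grows with
RSA depth even though record means continue to agree.

Rate summaries use the arithmetic mean, the **population** SD (divide by
n), and `cv = sd/mean`; the population/sample choice is stated here because
it is not derivable from the summaries themselves.

### Phase coherence and its significance

For two transforms on the same grid, the wavelet phase coherence at
frequency `f_k` is the magnitude of the time-averaged unit phasor of the
phase difference,

    C(f_k) = sqrt(<cos dPhi>^2 + <sin dPhi>^2),
    dPhi[k, n] = Phi2[k, n] - Phi1[k, n],

computed over times outside both COIs with nonzero amplitude in both
transforms. `C = 1` means a constant phase difference; a uniformly rotating
difference gives `C -> 0`. The circular mean `atan2(<sin>, <cos>)` is the
reported phase difference. The argument convention is pinned: in the
cardiorespiratory call the first argument is the IHR and the second the
respiration, so a positive phase difference means respiration leads. Phases
are taken from the full transforms of the two signals, not from extracted
ridges.

Finite records inflate coherence at low frequencies (fewer independent
cycles), so raw coherence is compared against a surrogate null.
`coherence_threshold()` builds 100 IAAFT surrogates of the second signal
(the first is left intact — randomising one member of the pair destroys the
phase relation while preserving each signal's amplitude spectrum and value
distribution), recomputes the coherence for each, and takes the
per-frequency 95th percentile (linear-interpolation quantile; with n = 100
this lies between the 95th and 96th order statistics). `apply_threshold()`
subtracts the threshold; adjusted coherence is deliberately **not** clipped
at zero, since near-zero adjusted values are informative and clipping would
bias band means upward.

The IAAFT iteration alternates imposing the target amplitude spectrum with
rank-remapping onto the original value distribution, stopping when the
relative spectral mismatch changes by less than `1e-6` or after 100
iterations; the returned series is the rank-remapped one, so its sorted
values equal the original's exactly.

A structural property of this test worth understanding: for a perfectly
monochromatic shared component, surrogates retain the spectral line and its
slowly evolving phase, so the null threshold at that frequency approaches
the raw coherence itself — a constant-frequency line can barely be declared
significant. Real PB drifts in frequency, which spreads the line over many
Fourier bins; surrogate phase randomisation then destroys the alignment and
the threshold drops while genuine phase locking survives. The synthetic
generator reproduces this drift (below) for exactly that reason.

### Band statistic and group comparisons

The **modulation band** 0.03-0.15 Hz summarises PB: `band_mean()` averages
the adjusted coherence over the grid frequencies in the closed band, giving
one value per subject and condition. Comparisons across the five exposure
conditions (NN, NHa, NH, HHa, HH) and across genotype groups (NOTCH4
GG/GA/AA; CAT CC/CT/TT, with the single-subject homozygous group merged
into the carriers when requested) use the Kruskal-Wallis test, with
pairwise Wilcoxon rank-sum follow-ups only when the omnibus test is
significant at `alpha = 0.05`. Rank-sum p-values are exact (enumeration)
for combined n up to 12 without ties, otherwise a tie- and
continuity-corrected normal approximation. No multiple-testing correction
is applied; reports state the number of tests performed. Missing
recordings are handled complete-case per comparison.

## The synthetic cohort generator

`generate_cohort()` exists so that every downstream stage can be exercised
and calibrated without recorded data. Per subject and condition it
synthesises:

* **respiration**: a carrier near 0.3 Hz (0.25 Hz in normoxia) whose
  instantaneous frequency performs a bounded random walk in 0.145-0.6 Hz;
  a PB envelope at `f_mod = 0.058 Hz` with depth `m_pb` and an apnoea duty
  fraction (`E(t) = (1 - m) + m * max(0, cos(phase_pb) - c)/(1 - c)`, with
  `c` chosen so the sub-threshold fraction of each cycle equals the duty);
  an explicit baseline component `b_base * cos(phase_pb)` — a pure AM
  carrier has no spectral line at the modulation frequency, only sidebands,
  whereas observed hypoxic respiration spectra show a genuine 0.058 Hz
  peak, physically the slow thoracic-volume drift across
  hyperpnoea/apnoea; an independent low-frequency baseline oscillator; and
  white noise.
* **heart rate**: `f_h(t) = f_heart + a_rsa sin(phase_resp) +
  a_pb_hr cos(phase_pb - phi_lag) + a_lf sin(phase_lf) + jitter`, clipped
  to 0.5-2 Hz; the ECG is a train of unit Gaussian pulses (SD 20 ms) at
  beat times where the integrated rate crosses successive integers.
* **LDF perfusion**: phase-diffusing narrowband oscillators centred in the
  cardiac, respiratory, myogenic (0.052-0.145 Hz), neurogenic
  (0.021-0.052 Hz) and endothelial (0.005-0.021 Hz) intervals, plus a
  PB-locked component with configurable lag.

Three design choices matter for interpreting test results:

1. **PB frequency drift.** The PB phase integrates a mean-reverting
   (Ornstein-Uhlenbeck) frequency process around `f_mod` (relaxation time
   60 s, stationary SD 4% of `f_mod`), shared by all channels of one
   record. Without drift the PB line is monochromatic and the IAAFT
   threshold at `f_mod` degenerates to ~0.9 (see above), which no real
   record shows. Mean reversion rather than a reflected random walk
   matters: a reflected walk's occupancy centres on its own realized
   wander, displacing the time-averaged spectral peak by a couple of grid
   steps in a non-negligible fraction of records, whereas the OU
   stationary law is centred on `f_mod` by construction, so spectral
   peaks stay within one grid step of the configured frequency (a
   generator contract that is unit-tested). With it, hypoxic-profile
   records yield adjusted band coherences around +0.1 to +0.2, the
   magnitude scale seen in group-mean spectra from real recordings.
2. **Independent LF variability.** Heart rate and respiration each carry an
   independent oscillator wandering in 0.04-0.15 Hz (`a_lf = 0.015` Hz,
   `b_lf = 0.075` a.u.), the Mayer-wave/baroreflex band. It competes with
   the PB component at `f_mod`, so cardiorespiratory coherence grades with
   PB depth instead of saturating at 1 — which is what makes
   genotype effects on PB depth detectable in the band statistic at all.
3. **Rate drift scale.** `freq_jitter_sd = 0.001 Hz/sqrt(s)` gives
   within-record rate SDs of roughly 0.04 Hz over 30 min, matching reported
   respiration-rate SDs; larger values would let normoxic respiration
   wander into the 0.145-0.15 Hz edge of the modulation band and create
   spurious "PB-like" coherence in the control condition.

Condition profiles set PB depth near zero in NN (exactly zero coupling:
normoxic controls show no PB), small in NHa, and large (`m_pb = 0.5`,
`a_pb_hr = 0.05` Hz) in NH, HHa and HH, together with the observed
direction of heart- and respiration-rate shifts under sustained hypoxia.
Genotype effects act multiplicatively on PB depth — NOTCH4 carriers (GA/AA)
scaled up in hypoxic conditions, CAT carriers (CT/TT) scaled down in
hypobaric conditions only — the simplest mechanism consistent with the
association being tested. Genotypes are quota-sampled to the empirical
margins of the study panel (NOTCH4 7/12/3, CAT 10/11/1 out of 22) and
permuted across subjects, so group sizes match an observed cohort rather
than fluctuating multinomially.

**What the generator does not emulate**: ECG morphology (P/T waves,
ectopy), intermittent episode structure of PB within a record (modulation
is continuous), closed-loop chemoreflex dynamics that generate PB,
movement artefacts (these are injected explicitly in tests), and any
altitude-of-residence structure. Passing tests therefore demonstrate that
the pipeline recovers the statistical structure it assumes — oscillations,
phase locking, genotype-dependent modulation depth — not that it would be
robust to every pathology of real recordings.

## Numerical choices and degenerate inputs

* Downsampling (1200 -> 40 Hz) uses a Blackman-windowed linear-phase FIR
  with cutoff at `0.45 * target_fs` (~74 dB stopband; a Hamming window
  caps near 53 dB), applied by FFT convolution with exact group-delay
  compensation, then integer decimation. Only integer factors are
  supported; upsampling is refused.
* Artefact repair interpolates linearly between nearest unmasked
  neighbours; boundary intervals extend the nearest unmasked value; a fully
  masked signal is an error. Detection (optional, off by default) flags
  robust z-scores above 6 and dilates runs by 0.25 s.
* Constant signals: MAD-based detection returns an empty mask; IAAFT
  refuses (no phase content); Kruskal-Wallis on all-identical values
  returns `H = 0, p = 1` explicitly (the chi-square form is 0/0 there).
* Ridge ties in the quadratic refinement (flat three-point neighbourhoods)
  fall back to the grid row; the refined frequency is clipped to the band.
* Surrogate seeds are derived as `seed + i` for the i-th surrogate, so
  thresholds are exactly reproducible from one master seed.
* Coherence entries at frequencies with zero jointly-valid times are `NA`
  and excluded from band means.

## Problem sizes used by the test suite

The validation studies run at reduced scales chosen to keep the full suite
in the tens of minutes on one CPU while preserving every contract being
tested: the coherence-identity check runs at the full 30 min x 40 Hz over
0.005-2 Hz; replicate studies (null calibration of the surrogate threshold,
PB parameter recovery, genotype size/power) use 10-30 min records generated
at 4 Hz and analysed at 1-2 Hz with transforms restricted to the bands
under test, 100 surrogates per threshold, and 20-100 replicates per claim.
The IAAFT iteration cap is 30 in the replicate studies (spectral mismatch
is already ~0.1-1% there) and 100 elsewhere. The generator invariant
`duration * f_mod >= 10` holds throughout.

## Known limitations

* The ridge extractor assumes one mode per band; crossing or merging modes
  (e.g. respiration entering the cardiac band) are out of scope.
* Surrogacy is one-sided (second signal only); two-sided surrogacy would
  give slightly different thresholds.
* The modulation-band mean treats all grid frequencies equally; a
  PB-tracking statistic could be more sensitive but would not correspond
  to the band statistic being reproduced.
* p-values from the chi-square approximation to Kruskal-Wallis are
  approximate for very small groups; the rank-sum follow-ups switch to
  exact enumeration where feasible.
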