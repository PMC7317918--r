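# cardiocoh

Wavelet phase coherence analysis of cardiorespiratory dynamics.

## The problem

Under hypoxia (e.g. at high altitude), breathing can switch into **periodic
breathing (PB)**: regular respiration is amplitude-modulated at roughly
0.058 Hz, with bouts of hyperventilation alternating with apnoea. The same
slow rhythm modulates the heart rate. Quantifying whether — and how
strongly — the two signals share this rhythm, and whether the strength of
that sharing differs between exposure conditions or between carriers of
particular gene variants (NOTCH4 rs367398, CAT rs1001179), requires a
time-frequency analysis that tolerates the frequency drift inherent in
physiological oscillations.

`cardiocoh` implements that analysis end to end for researchers working
with simultaneous ECG, respiratory-effort and laser-Doppler perfusion
recordings:

* continuous wavelet transforms on a logarithmic frequency grid
  (lognormal and Morlet analytic wavelets, 32 voices/octave, cone-of-
  influence handling);
* ridge extraction of instantaneous heart rate (0.5–2 Hz) and respiration
  rate (0.145–0.6 Hz), plus the classical R–R-interval rate as a
  cross-check;
* **wavelet phase coherence** with circular phase differences:

  `C(f_k) = sqrt(<cos dPhi>² + <sin dPhi>²)`, `dPhi = Phi₂ − Phi₁`,

  the magnitude of the time-averaged unit phasor of the phase difference
  at each frequency (1 = locked, → 0 = drifting);
* significance by **IAAFT surrogates**: per-frequency 95th-percentile
  thresholds from 100 iterative amplitude-adjusted Fourier-transform
  surrogates, subtracted from the raw coherence;
* the **modulation-band statistic**: mean adjusted coherence over
  0.03–0.15 Hz, one number per subject × condition quantifying PB;
* nonparametric group analysis (Kruskal–Wallis, Wilcoxon rank-sum
  follow-ups, no multiplicity correction) across exposure conditions and
  genotype groups;
* a synthetic cohort generator that emulates the assumed signal structure
  (PB envelope with apnoea epochs, RSA, Mayer-wave-band variability,
  vasomotion bands, genotype-dependent PB depth) so the whole pipeline is
  testable and calibratable without access to recorded data.

## Worked example

Synthesise one hypoxic-profile recording (30 min; PB depth 0.5 at
0.058 Hz), compute the cardiorespiratory coherence in the modulation band,
and test it against its surrogate threshold:

```r
library(cardiocoh)

cfg <- synthetic_config(duration_s = 1800, fs = 4, m_pb = 0.5,
                        a_pb_hr = 0.05, b_base = 0.3, apnoea_duty = 0.25,
                        seed = 42)
resp <- generate_respiration(cfg)
ihr  <- generate_heart(cfg, with_ecg = FALSE)$ihr

resp1 <- resample_signal(resp, 1)      # 1 Hz is ample for a 0.15 Hz band
ihr1  <- resample_signal(ihr, 1)
tf_ihr  <- cwt_tfr(ihr1,  fmin = 0.03, fmax = 0.15)
tf_resp <- cwt_tfr(resp1, fmin = 0.03, fmax = 0.15)

coh <- phase_coherence(tf_ihr, tf_resp)   # positive phase = resp leads
thr <- coherence_threshold(ihr1, resp1, n = 100, seed = 42,
                           fmin = 0.03, fmax = 0.15)
coh <- apply_threshold(coh, thr)

k <- which.min(abs(coh$freqs - 0.058))
cat(sprintf("raw coherence at %.4f Hz: %.3f (threshold %.3f)\n",
            coh$freqs[k], coh$raw_coh[k], coh$threshold[k]))
cat(sprintf("band (0.03-0.15 Hz) mean adjusted coherence: %.3f\n",
            band_mean(coh)))
cat(sprintf("phase difference at the PB frequency: %.2f rad (%s)\n",
            coh$phase_diff[k], lead_lag(coh$phase_diff[k])))
```

```
raw coherence at 0.0575 Hz: 0.999 (threshold 0.583)
band (0.03-0.15 Hz) mean adjusted coherence: 0.220
phase difference at the PB frequency: 0.30 rad (signal2_leads)
```

Reading the output: the heart rate and respiration are almost perfectly
phase-locked at the PB frequency (0.999), far above what chance alignment
of two signals with these spectra produces (0.583), leaving a strongly
positive adjusted band mean (0.220) — this record would count as showing
periodic breathing. The +0.30 rad phase difference says respiration leads
the heart-rate modulation, here by exactly the lag the generator imposed.
A normoxic-profile record (`m_pb = 0`, `a_pb_hr = 0`, `b_base = 0`)
yields a negative band mean: no significant coherence.

The full pipeline — rate summaries, normalised group-mean spectra,
per-record coherence with thresholds, condition and genotype
Kruskal–Wallis tables, TSV outputs and a JSON manifest — runs from one
configuration object:

```r
res <- run_pipeline(run_config(
  seed = 1,
  synthetic = list(n_subjects = 22,
                   conditions = c("NN", "NHa", "NH", "HHa", "HH"))),
  outdir = "out")
print(res)
```

`vignettes/cardiocoh-methods.Rmd` documents the model, every tunable
parameter, the generator's design and its limitations.

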