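# shared fixtures: short deterministic signals built in code

sine_signal <- function(freq, dur, fs, phase = 0, amp = 1, label = "x") {
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  uniform_signal(amp * sin(2 * pi * freq * tt + phase), fs = fs, label = label)
}

noise_signal <- function(dur, fs, seed, sd = 1, label = "x") {
  set.seed(seed)
  uniform_signal(rnorm(round(dur * fs), 0, sd), fs = fs, label = label)
}

# dominant periodogram frequency (independent spectral oracle)
periodogram_peak <- function(sig) {
  sp <- spec.pgram(ts(sig$samples, frequency = sig$fs), plot = FALSE,
                   taper = 0, detrend = TRUE)
  sp$freq[which.max(sp$spec)]
}

# band power from the periodogram (independent of the wavelet machinery)
periodogram_band_power <- function(sig, f_lo, f_hi) {
  sp <- spec.pgram(ts(sig$samples, frequency = sig$fs), plot = FALSE,
                   taper = 0, detrend = TRUE)
  sum(sp$spec[sp$freq >= f_lo & sp$freq <= f_hi])
}

mask_logical_for_test <- function(mask, n) cardiocoh:::mask_logical(mask, n)
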