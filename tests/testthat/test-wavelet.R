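test_that("preprocessing removes trend and out-of-band power, keeps in-band amplitude", {
  fs <- 10
  tt <- seq(0, 300 - 1 / fs, by = 1 / fs)
  ramp <- uniform_signal(0.5 + 0.02 * tt, fs, "x")
  out <- preprocess_signal(ramp, 0.05, 2)
  expect_lt(abs(mean(out$samples)), 1e-8)
  expect_lt(abs(unname(coef(lm(out$samples ~ tt))[2])), 1e-6)
  # deep sub-band tone is attenuated > 40 dB in amplitude projection,
  # in-band tone survives
  mix <- uniform_signal(sin(2 * pi * 0.004 * tt) + sin(2 * pi * 0.3 * tt),
                        fs, "x")
  filt <- preprocess_signal(mix, 0.05, 2)
  proj <- function(x, f) {
    b <- sin(2 * pi * f * tt)
    abs(sum(x * b)) / sum(b * b)
  }
  expect_lt(proj(filt$samples, 0.004) / proj(mix$samples, 0.004), 0.01)
  core <- 500:2500                             # away from record edges
  pure <- sin(2 * pi * 0.3 * tt)
  expect_lt(max(abs(filt$samples[core] - pure[core])) , 0.05)
  expect_error(preprocess_signal(ramp, 0.005, 2), "3/fmin")
})

test_that("CWT concentrates a tone on the nearest grid row with stable unit amplitude", {
  s <- sine_signal(0.1, 600, 4)
  tfr <- cwt_tfr(s, fmin = 0.02, fmax = 1)
  expect_s3_class(tfr, "wavelet_tfr")
  k_star <- which.min(abs(tfr$freqs - 0.1))
  amp <- Mod(tfr$coeffs)
  valid_cols <- which(!tfr$coi_mask[k_star, ])
  expect_true(all(apply(amp[, valid_cols], 2, which.max) == k_star))
  # amplitude estimate ~1 and stable over non-COI times (within 1 %)
  row <- amp[k_star, valid_cols]
  expect_lt(max(abs(row - 1)), 0.01)
  # linearity
  s3 <- sine_signal(0.1, 600, 4, amp = 3)
  tfr3 <- cwt_tfr(s3, fmin = 0.02, fmax = 1)
  expect_equal(tfr3$coeffs, 3 * tfr$coeffs, tolerance = 1e-8)
  # zero signal -> zero coefficients (skip detrending, which needs variance)
  z <- uniform_signal(rep(0, 2400), 4, "x")
  tfz <- cwt_tfr(z, fmin = 0.02, fmax = 1, preprocess = FALSE)
  expect_equal(max(Mod(tfz$coeffs)), 0)
})

test_that("two separated tones give two ridges with a clean gap between them", {
  fs <- 4
  tt <- seq(0, 600 - 1 / fs, by = 1 / fs)
  s <- uniform_signal(sin(2 * pi * 0.05 * tt) + sin(2 * pi * 0.35 * tt),
                      fs, "x")
  tfr <- cwt_tfr(s, fmin = 0.02, fmax = 1)
  p <- time_average_power(tfr)
  k1 <- which.min(abs(p$freqs - 0.05))
  k2 <- which.min(abs(p$freqs - 0.35))
  mid <- which(p$freqs > 0.1 & p$freqs < 0.2)
  expect_gt(p$power[k1], 0.4)
  expect_gt(p$power[k2], 0.4)
  # no spurious mode between the tones above 10% of the peaks (power: 1%)
  expect_lt(max(p$power[mid]), 0.01 * min(p$power[k1], p$power[k2]))
})

test_that("time-averaged power is quadratic in amplitude and COI-aware", {
  s1 <- sine_signal(0.2, 400, 4)
  s2 <- sine_signal(0.2, 400, 4, amp = 2)
  p1 <- time_average_power(cwt_tfr(s1, fmin = 0.05, fmax = 1))
  p2 <- time_average_power(cwt_tfr(s2, fmin = 0.05, fmax = 1))
  expect_equal(p2$power, 4 * p1$power, tolerance = 1e-6)
  expect_true(all(p1$n_valid <= length(s1$samples)))
  expect_true(all(p1$n_valid > 0))
})

test_that("normalisation gives unit log-frequency integral and scale invariance", {
  s <- sine_signal(0.2, 400, 4)
  sp <- normalise_spectrum(time_average_power(cwt_tfr(s, fmin = 0.05, fmax = 1)))
  dlnf <- log(2) / sp$params$nv
  expect_equal(sum(sp$power * dlnf, na.rm = TRUE), 1, tolerance = 1e-12)
  s10 <- sine_signal(0.2, 400, 4, amp = 10)
  sp10 <- normalise_spectrum(time_average_power(cwt_tfr(s10, fmin = 0.05, fmax = 1)))
  expect_equal(sp10$power, sp$power, tolerance = 1e-8)
})

test_that("group means of spectra are pointwise means on a shared grid", {
  a <- normalise_spectrum(time_average_power(cwt_tfr(
    sine_signal(0.1, 400, 4), fmin = 0.05, fmax = 1)))
  b <- normalise_spectrum(time_average_power(cwt_tfr(
    sine_signal(0.3, 400, 4), fmin = 0.05, fmax = 1)))
  gm <- group_mean_spectra(list(a, b))
  expect_equal(gm$power, (a$power + b$power) / 2, tolerance = 1e-12)
  expect_equal(group_mean_spectra(list(a))$power, a$power)
  bad <- b
  bad$freqs <- bad$freqs * 1.01
  expect_error(group_mean_spectra(list(a, bad)), "grid")
})

test_that("morlet and lognormal wavelets localise the same tone consistently", {
  s <- sine_signal(0.25, 400, 4)
  for (w in c("lognormal", "morlet")) {
    tfr <- cwt_tfr(s, fmin = 0.05, fmax = 1, wavelet = w)
    p <- time_average_power(tfr)
    # peak lands on the grid row nearest the tone (within one voice)
    expect_lt(abs(log2(p$freqs[which.max(p$power)] / 0.25)), 1 / 32)
  }
})

test_that("white-noise power per octave is flat under amplitude normalisation", {
  # with peak-1 (amplitude) wavelet windows, captured noise power scales with
  # the window bandwidth, i.e. with frequency: power/f should be flat
  set.seed(99)
  acc <- 0
  for (i in 1:20) {
    n <- noise_signal(400, 4, seed = i)
    p <- time_average_power(cwt_tfr(n, fmin = 0.05, fmax = 1))
    acc <- acc + p$power / p$freqs
  }
  acc <- acc / 20
  expect_lt(max(acc) / min(acc), 3)
})
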