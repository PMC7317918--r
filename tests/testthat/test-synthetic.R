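test_that("generation is bit-reproducible from the seed", {
  cfg <- synthetic_config(duration_s = 200, fs = 8, seed = 10)
  expect_identical(generate_respiration(cfg)$samples,
                   generate_respiration(cfg)$samples)
  h1 <- generate_heart(cfg)
  h2 <- generate_heart(cfg)
  expect_identical(h1$ihr$samples, h2$ihr$samples)
  expect_identical(h1$ecg$samples, h2$ecg$samples)
  cfg2 <- synthetic_config(duration_s = 200, fs = 8, seed = 11)
  expect_false(identical(generate_respiration(cfg2)$samples,
                         generate_respiration(cfg)$samples))
})

test_that("degenerate respiration reduces to a pure carrier", {
  cfg <- synthetic_config(duration_s = 400, fs = 8, m_pb = 0, b_base = 0,
                          b_lf = 0, noise_sd = 0, apnoea_duty = 0,
                          freq_jitter_sd = 0, seed = 3)
  r <- generate_respiration(cfg)
  expect_equal(periodogram_peak(r), 0.3, tolerance = 0.31 - 0.3)
  expect_equal(max(abs(r$samples)), 1, tolerance = 1e-3)
})

test_that("apnoea epochs occupy the configured fraction of each PB cycle", {
  cfg <- synthetic_config(duration_s = 600, fs = 40, m_pb = 0.9,
                          apnoea_duty = 0.3, b_base = 0, b_lf = 0,
                          noise_sd = 0.01, seed = 4)
  r <- generate_respiration(cfg)
  w <- matrix(r$samples, nrow = 40)              # 1-s windows
  rms <- sqrt(colMeans(w^2))
  expect_lt(abs(mean(rms < 0.1 * max(rms)) - 0.3), 0.05)
  expect_error(synthetic_config(apnoea_duty = 1), "apnoea_duty")
})

test_that("heart generator honours its rate contracts", {
  cfg0 <- synthetic_config(duration_s = 300, fs = 40, a_rsa = 0, a_pb_hr = 0,
                           a_lf = 0, noise_sd = 0, freq_jitter_sd = 0,
                           m_pb = 0, apnoea_duty = 0, seed = 6)
  h0 <- generate_heart(cfg0)
  # all beat intervals equal 1/f_heart when every modulation is off
  pk <- which(h0$ecg$samples > 0.5 &
                h0$ecg$samples >= c(-Inf, h0$ecg$samples[-length(h0$ecg$samples)]) &
                h0$ecg$samples > c(h0$ecg$samples[-1], -Inf))
  expect_equal(sd(diff(pk)) / 40, 0, tolerance = 2 / 40)
  expect_equal(mean(h0$ihr$samples), 1, tolerance = 0.01)
  # PB heart-rate modulation shows up at f_mod in the rate spectrum
  cfg1 <- synthetic_config(duration_s = 600, fs = 8, a_pb_hr = 0.1, a_rsa = 0,
                           a_lf = 0, noise_sd = 0, freq_jitter_sd = 0, seed = 7)
  ihr <- generate_heart(cfg1, with_ecg = FALSE)$ihr
  expect_lt(abs(periodogram_peak(ihr) - 0.058), 0.01)
  expect_equal(mean(ihr$samples), 1, tolerance = 0.01)
})

test_that("LDF band powers scale with the configured amplitudes", {
  cfg <- synthetic_config(duration_s = 900, fs = 4, noise_sd = 0.01, seed = 8)
  amp1 <- c(cardiac = 0, respiratory = 0, myogenic = 0.5, neurogenic = 0,
            endothelial = 0, pb = 0)
  amp2 <- amp1; amp2[["myogenic"]] <- 1
  l1 <- generate_ldf(cfg, amplitudes = amp1)
  l2 <- generate_ldf(cfg, amplitudes = amp2)
  p1 <- periodogram_band_power(l1, 0.04, 0.16)
  p2 <- periodogram_band_power(l2, 0.04, 0.16)
  expect_equal(p2 / p1, 4, tolerance = 0.4)    # power ~ amplitude^2
  # all-zero amplitudes leave pure noise
  zero <- amp1; zero[] <- 0
  ln <- generate_ldf(cfg, amplitudes = zero)
  expect_lt(sd(ln$samples), 0.02)
})

test_that("cohorts share genotypes across conditions with quota margins", {
  coh <- generate_cohort(n_subjects = 22, conditions = c("NN", "NH"),
                         seed = 5,
                         base_cfg = synthetic_config(duration_s = 200, fs = 4),
                         channels = "resp")
  expect_length(coh, 44)
  subj <- vapply(coh, `[[`, character(1), "subject_id")
  for (s in unique(subj)) {
    recs <- coh[subj == s]
    expect_identical(recs[[1]]$genotypes, recs[[2]]$genotypes)
  }
  # quota sampling reproduces the panel's genotype counts exactly
  gt <- vapply(coh[seq(1, 44, 2)], function(r) r$genotypes[["NOTCH4"]],
               character(1))
  cnt <- table(gt)
  expect_equal(unname(cnt[c("GG", "GA", "AA")]), c(7L, 12L, 3L),
               ignore_attr = TRUE)
  # determinism
  coh2 <- generate_cohort(n_subjects = 22, conditions = c("NN", "NH"),
                          seed = 5,
                          base_cfg = synthetic_config(duration_s = 200, fs = 4),
                          channels = "resp")
  expect_identical(coh[[1]]$signals$resp$samples,
                   coh2[[1]]$signals$resp$samples)
})

test_that("genotype effects scale PB depth only in the conditions they act on", {
  base_cfg <- synthetic_config(duration_s = 200, fs = 4)
  expect_warning(
    generate_cohort(n_subjects = 6, conditions = "HH",
                    effect_sizes = c(NOTCH4 = 3, CAT = 1), seed = 2,
                    base_cfg = base_cfg, channels = "resp"),
    "clipped")
  # cfg invariants
  expect_error(synthetic_config(f_resp = 0.05), "f_mod < f_resp")
  expect_error(synthetic_config(duration_s = 100, fs = 4), "PB cycles")
})

test_that("spectral peaks of generated signals sit on their configured frequencies", {
  # despite the bounded drifts, the time-averaged wavelet spectra must peak
  # within one grid step (32 voices/octave) of the configured frequencies
  for (seed in 1:5) {
    cfg <- synthetic_config(duration_s = 1800, fs = 4, m_pb = 0.5,
                            a_pb_hr = 0.05, b_base = 0.3,
                            apnoea_duty = 0.25, seed = seed)
    r <- resample_signal(generate_respiration(cfg), 1)
    h <- resample_signal(generate_heart(cfg, with_ecg = FALSE)$ihr, 1)
    for (s in list(r, h)) {
      p <- time_average_power(cwt_tfr(s, fmin = 0.03, fmax = 0.15))
      f_peak <- p$freqs[which.max(p$power)]
      expect_lte(abs(log2(f_peak / 0.058)), 1.5 / 32)
    }
  }
})

test_that("genotype tables round-trip through the TSV sidecar", {
  coh <- generate_cohort(n_subjects = 4, conditions = "NN", seed = 9,
                         base_cfg = synthetic_config(duration_s = 200, fs = 4),
                         channels = "resp")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(coh, path)
  back <- read_genotypes(path)
  expect_setequal(names(back), unique(vapply(coh, `[[`, character(1),
                                             "subject_id")))
  expect_identical(back[["S01"]][["NOTCH4"]], coh[[1]]$genotypes[["NOTCH4"]])
})
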