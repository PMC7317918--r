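test_that("TSV round-trip reproduces signals bit-exactly and infers fs", {
  set.seed(42)
  tt <- seq(0, 2 - 1 / 1200, by = 1 / 1200)
  sigs <- list(ecg = uniform_signal(rnorm(length(tt)), 1200, "ecg"),
               resp = uniform_signal(sin(2 * pi * 0.3 * tt), 1200, "resp"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signals(sigs, path)
  back <- read_signals(path)
  expect_named(back, c("ecg", "resp"))
  expect_equal(back$ecg$fs, 1200, tolerance = 1e-9)
  expect_identical(back$ecg$samples, sigs$ecg$samples)
  expect_identical(back$resp$samples, sigs$resp$samples)
})

test_that("jittered time grids and missing headers are format errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tt <- (0:99) / 100
  tt[50] <- tt[50] + 1e-4                      # > 1e-6 relative jitter
  writeLines(c("time\tecg", paste(tt, rnorm(100), sep = "\t")), path)
  expect_error(read_signals(path), "non-uniform")
  writeLines(c("ecg\tresp", paste(rnorm(5), rnorm(5), sep = "\t")), path)
  expect_error(read_signals(path), "header")
})

test_that("downsampling 1200 to 40 Hz preserves in-band content and kills the stopband", {
  s <- sine_signal(0.3, 60, 1200, label = "resp")
  r <- resample_signal(s, 40)
  expect_equal(r$fs, 40)
  expect_equal(length(r$samples), 2400)
  expect_equal(periodogram_peak(r), 0.3, tolerance = 1e-6)
  # white noise: power above the 18 Hz cutoff must be ~0 after filtering
  n <- noise_signal(30, 1200, seed = 7)
  rn <- resample_signal(n, 40)
  hi <- periodogram_band_power(rn, 19, 20)
  lo <- periodogram_band_power(rn, 1, 17)
  expect_lt(hi / lo, 1e-3)
  # identity at equal rates; idempotence at a fixed target
  expect_identical(resample_signal(s, 1200)$samples, s$samples)
  expect_error(resample_signal(r, 80), "upsampling")
})

test_that("artefact repair interpolates linearly and leaves the rest bit-exact", {
  s <- uniform_signal(c(0, 1, 99, 3), fs = 1, label = "x")
  fixed <- repair_artefacts(s, artefact_mask(cbind(3L, 4L)))
  expect_equal(fixed$samples, c(0, 1, 2, 3))
  set.seed(1)
  big <- uniform_signal(rnorm(500), 10, "x")
  m <- artefact_mask(cbind(c(100L, 301L), c(120L, 310L)))
  rep <- repair_artefacts(big, m)
  keep <- !mask_logical_for_test(m, 500)
  expect_identical(rep$samples[keep], big$samples[keep])
  # empty mask is the identity
  expect_identical(repair_artefacts(big, artefact_mask())$samples, big$samples)
  # boundary interval: constant extension of nearest unmasked value
  edge <- repair_artefacts(uniform_signal(c(50, 2, 3, 4), 1, "x"),
                           artefact_mask(cbind(1L, 2L)))
  expect_equal(edge$samples, c(2, 2, 3, 4))
  expect_error(repair_artefacts(s, artefact_mask(cbind(1L, 5L))), "fully masked")
})

test_that("robust artefact detection flags spikes, not clean noise", {
  set.seed(3)
  s <- uniform_signal(rnorm(4000), 40, "ldf_left")
  expect_equal(nrow(detect_artefacts(s, 6)$intervals), 0L)
  x <- s$samples
  x[2000] <- 50
  sp <- uniform_signal(x, 40, "ldf_left")
  m <- detect_artefacts(sp, 6)
  expect_equal(nrow(m$intervals), 1L)
  expect_true(m$intervals[1, 1] <= 2000 && m$intervals[1, 2] > 2000)
  # spike train masked at every spike: repaired max falls well below spikes
  y <- rnorm(4000)
  spikes <- seq(200, 3800, by = 400)
  y[spikes] <- 30
  st <- uniform_signal(y, 40, "ldf_left")
  mm <- detect_artefacts(st, 6)
  repaired <- repair_artefacts(st, mm)
  expect_lt(max(abs(repaired$samples)), 15)
  # constant signal: MAD = 0, empty mask
  expect_equal(nrow(detect_artefacts(uniform_signal(rep(1, 100), 1, "x"))$intervals), 0L)
})

test_that("sidecar artefact masks map seconds to sample indices", {
  s <- uniform_signal(rnorm(400), 40, "ldf_left")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\tstart_s\tend_s", "ldf_left\t1.0\t2.0", "ecg\t0\t1"), path)
  m <- read_artefact_mask(path, s)
  expect_equal(nrow(m$intervals), 1L)
  expect_equal(unname(m$intervals[1, ]), c(41L, 81L))
})
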