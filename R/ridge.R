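#' Extract an instantaneous-frequency ridge from a wavelet transform
#'
#' Traces the amplitude-maximal, continuity-constrained path of one
#' oscillatory mode through a frequency band of the transform. The path is
#' found globally by dynamic programming: it maximises the summed (max-
#' normalised) coefficient amplitude minus a quadratic jump penalty
#' `lambda * (delta log2 f)^2` between consecutive time steps. The ridge
#' frequency is refined by quadratic interpolation across the three grid
#' rows around the path; the instantaneous phase is the argument of the
#' coefficient on the path.
#'
#' Typical bands: instantaneous heart rate 0.5-2 Hz from the ECG transform;
#' instantaneous respiration rate 0.145-0.6 Hz from the respiratory-effort
#' transform.
#'
#' @param tfr A [cwt_tfr()] result.
#' @param band Numeric `c(f_lo, f_hi)` in Hz, inside the transform range.
#' @param lambda Continuity penalty per octave^2 (default 2).
#' @return A `wavelet_ridge` object: `inst_freq`, `inst_phase` (wrapped to
#'   `(-pi, pi]`), `inst_amp`, `times`, `band`, `valid_mask` (non-COI), and
#'   the grid step `dlog2f`.
#' @export
extract_ridge <- function(tfr, band, lambda = 2) {
  stopifnot(inherits(tfr, "wavelet_tfr"), length(band) == 2L, band[1] < band[2])
  rows <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  if (!length(rows)) stop("band contains no transform frequencies")
  A <- Mod(tfr$coeffs[rows, , drop = FALSE])
  amax <- max(A)
  if (amax == 0) stop("band is identically zero; no ridge to extract")
  path <- ridge_dp(A / amax, log2(tfr$freqs[rows]), lambda)
  k <- rows[path]
  n <- length(path)
  idx <- cbind(k, seq_len(n))
  # quadratic refinement in log2 f around the path (interior rows only)
  dl <- 1 / tfr$params$nv
  delta <- numeric(n)
  interior <- k > 1L & k < length(tfr$freqs)
  if (any(interior)) {
    ii <- which(interior)
    a <- Mod(tfr$coeffs)[cbind(k[ii] - 1L, ii)]
    b <- Mod(tfr$coeffs)[cbind(k[ii], ii)]
    c2 <- Mod(tfr$coeffs)[cbind(k[ii] + 1L, ii)]
    den <- a - 2 * b + c2
    d <- ifelse(abs(den) > 0, 0.5 * (a - c2) / den, 0)
    delta[ii] <- pmin(pmax(d, -0.5), 0.5)
  }
  inst_freq <- pmin(pmax(2^(log2(tfr$freqs[k]) + delta * dl),
                         band[1]), band[2])
  inst_phase <- Arg(tfr$coeffs[idx])
  inst_amp <- Mod(tfr$coeffs[idx])
  valid <- !tfr$coi_mask[idx]
  structure(list(inst_freq = inst_freq, inst_phase = inst_phase,
                 inst_amp = inst_amp, times = tfr$times, band = band,
                 valid_mask = valid, dlog2f = dl),
            class = "wavelet_ridge")
}

#' @export
print.wavelet_ridge <- function(x, ...) {
  cat(sprintf(
    "<wavelet_ridge> band %g-%g Hz, %d times (%d valid); mean freq %.3f Hz\n",
    x$band[1], x$band[2], length(x$times), sum(x$valid_mask),
    mean(x$inst_freq[x$valid_mask])))
  invisible(x)
}

#' Instantaneous heart rate from an ECG signal
#'
#' The ECG's wavelet transform is a comb of near-equal-amplitude lines (the
#' beat fundamental and its harmonics), so an unconstrained
#' amplitude-maximal ridge can lock onto a harmonic. This operation first
#' locates the cardiac fundamental -- the lowest local maximum of the
#' time-averaged coefficient amplitude reaching at least half the band
#' maximum within `band` -- and then runs [extract_ridge()] in a +/- 0.5
#' octave window around it (clipped to `band`), which excludes the first
#' harmonic for physiological rates.
#'
#' @param ecg A [uniform_signal()] ECG.
#' @param band Search band in Hz (default the cardiac 0.5-2 Hz).
#' @param fs_out Output rate for the IHR series (default 40 Hz).
#' @param lambda Ridge continuity penalty, see [extract_ridge()].
#' @param ... Transform parameters passed to [cwt_tfr()].
#' @return A list with `ihr` (a [uniform_signal()]) and `ridge` (the
#'   underlying `wavelet_ridge`).
#' @export
ihr_from_ecg <- function(ecg, band = c(0.5, 2), fs_out = 40, lambda = 2,
                         ...) {
  stopifnot(inherits(ecg, "uniform_signal"))
  tfr <- cwt_tfr(ecg, fmin = band[1] / 1.2,
                 fmax = min(band[2] * 1.2, ecg$fs / 2), ...)
  rows <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  amp <- Mod(tfr$coeffs[rows, , drop = FALSE])
  amp[tfr$coi_mask[rows, , drop = FALSE]] <- NA_real_
  prof <- rowMeans(amp, na.rm = TRUE)
  K <- length(prof)
  is_max <- prof >= c(-Inf, prof[-K]) & prof > c(prof[-1], -Inf) &
    prof >= 0.5 * max(prof, na.rm = TRUE)
  if (!any(is_max, na.rm = TRUE)) stop("no cardiac mode found in band")
  f_fund <- tfr$freqs[rows[which(is_max)[1L]]]
  sub_band <- c(max(band[1], f_fund / sqrt(2)), min(band[2], f_fund * sqrt(2)))
  ridge <- extract_ridge(tfr, sub_band, lambda = lambda)
  list(ihr = rate_series(ridge, fs_out = fs_out, label = "ihr"),
       ridge = ridge)
}

#' Instantaneous-rate time series from a ridge
#'
#' Resamples the ridge's instantaneous frequency onto a uniform grid at
#' `fs_out`, restricted to the COI-valid span (edges trimmed).
#'
#' @param ridge A [extract_ridge()] result.
#' @param fs_out Output sampling rate in Hz (default 40).
#' @param label Channel label, typically `"ihr"` or `"resp_rate"`.
#' @return A [uniform_signal()].
#' @export
rate_series <- function(ridge, fs_out = 40, label = "ihr") {
  stopifnot(inherits(ridge, "wavelet_ridge"))
  v <- which(ridge$valid_mask)
  if (length(v) < 2L) stop("ridge has fewer than 2 valid times")
  tv <- ridge$times[v]
  tout <- seq(tv[1L], tv[length(tv)], by = 1 / fs_out)
  y <- approx(tv, ridge$inst_freq[v], xout = tout, ties = "ordered")$y
  uniform_signal(y, fs = fs_out, label = label, t0 = tout[1L])
}

#' Summary statistics of an instantaneous-rate series
#'
#' Arithmetic mean, population standard deviation (divide by n), and the
#' coefficient of variation `cv = sd / mean`. The CV is `NA` (flagged) when
#' the mean is not positive.
#'
#' @param series A [uniform_signal()] (or plain numeric vector) of rates.
#' @return A `rate_summary` list: `mean`, `sd`, `cv`, `n`.
#' @export
rate_summary <- function(series) {
  x <- if (inherits(series, "uniform_signal")) series$samples else
    as.numeric(series)
  if (length(x) < 2L) stop("need at least 2 samples")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  structure(list(mean = m, sd = s,
                 cv = if (m > 0) s / m else NA_real_, n = length(x)),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("<rate_summary> mean %.4f Hz, sd %.4f Hz, cv %.4f (n = %d)\n",
              x$mean, x$sd, if (is.na(x$cv)) NA else x$cv, x$n))
  invisible(x)
}

#' Heart rate from consecutive R-R intervals
#'
#' Detects R peaks as local maxima above an adaptive threshold
#' (median + 4 MAD) separated by at least `min_rr_s`, then defines the heart
#' rate between consecutive peaks as the inverse of the R-R interval, held
#' constant over that interval. This is the classical beat-to-beat estimator
#' and serves as an independent cross-check of the ridge-extracted
#' instantaneous heart rate.
#'
#' @param ecg A [uniform_signal()] containing beat pulses.
#' @param min_rr_s Minimum R-R interval in seconds (default 0.3).
#' @return A piecewise-constant [uniform_signal()] labelled `"ihr"`, at the
#'   ECG sampling rate, covering the span between the first and last peak;
#'   with attribute `peaks` giving the peak times in seconds.
#' @export
rr_heart_rate <- function(ecg, min_rr_s = 0.3) {
  stopifnot(inherits(ecg, "uniform_signal"), min_rr_s > 0)
  x <- ecg$samples
  thr <- median(x) + 4 * mad(x)
  n <- length(x)
  loc <- which(x > thr &
                 x >= c(-Inf, x[-n]) &
                 x > c(x[-1], -Inf))
  if (length(loc) >= 2L) {
    # enforce the refractory interval, keeping the larger of close peaks
    keep <- loc[1L]
    for (i in loc[-1L]) {
      last <- keep[length(keep)]
      if ((i - last) / ecg$fs >= min_rr_s) keep <- c(keep, i)
      else if (x[i] > x[last]) keep[length(keep)] <- i
    }
    loc <- keep
  }
  if (length(loc) < 2L) stop("fewer than 2 R peaks detected")
  tpk <- ecg$t0 + (loc - 1L) / ecg$fs
  rate <- 1 / diff(tpk)
  idx <- loc[1L]:loc[length(loc)]
  seg <- findInterval(idx, loc, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), length(rate))
  out <- uniform_signal(rate[seg], fs = ecg$fs, label = "ihr", t0 = tpk[1L])
  attr(out, "peaks") <- tpk
  out
}

#' Export a ridge as TSV
#' @param ridge A `wavelet_ridge`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ridge <- function(ridge, path) {
  write.table(data.frame(time = ridge$times, freq = ridge$inst_freq,
                         phase = ridge$inst_phase, amp = ridge$inst_amp),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
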