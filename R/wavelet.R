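#' Detrend and band-limit a signal before wavelet analysis
#'
#' Subtracts a third-order polynomial trend fitted by least squares, then
#' band-passes to `[fmin, fmax]` by zeroing Fourier components outside the
#' band. This removes the slow non-oscillatory drift that would otherwise
#' leak power into the lowest wavelet scales.
#'
#' @param x A [uniform_signal()].
#' @param fmin,fmax Band edges in Hz; `fmin < fmax <= fs/2`.
#' @return The preprocessed `uniform_signal`.
#' @export
preprocess_signal <- function(x, fmin = 0.005, fmax = 2) {
  stopifnot(inherits(x, "uniform_signal"))
  if (!(fmin < fmax)) stop("fmin must be < fmax")
  if (fmax > x$fs / 2 + 1e-12) stop("fmax exceeds the Nyquist frequency")
  if (signal_duration(x) < 3 / fmin)
    stop("signal shorter than 3/fmin s: too few cycles at fmin")
  n <- length(x$samples)
  tt <- seq_len(n) / x$fs
  fit <- lm(y ~ poly(tt, 3), data = data.frame(y = x$samples, tt = tt))
  r <- x$samples - predict(fit)
  X <- fft(r)
  f <- (seq_len(n) - 1) / n * x$fs
  f <- pmin(f, x$fs - f)                       # two-sided frequency magnitude
  X[f < fmin | f > fmax] <- 0
  uniform_signal(Re(fft(X, inverse = TRUE)) / n, fs = x$fs,
                 label = x$label, t0 = x$t0)
}

# Frequency-domain wavelet windows, peak value 1 at nu = f/fc = 1, analytic
# (identically zero for nu <= 0).
#  - lognormal: Gaussian in log-frequency, width set by f0
#  - morlet: Gaussian in linear frequency centred at nu = 1
wavelet_window <- function(nu, type, f0) {
  w <- numeric(length(nu))
  pos <- nu > 0
  if (type == "lognormal") {
    w[pos] <- exp(-(2 * pi * f0)^2 / 2 * log(nu[pos])^2)
  } else {
    w[pos] <- exp(-(2 * pi * f0)^2 / 2 * (nu[pos] - 1)^2)
  }
  w
}

# e-folding time of the mother wavelet envelope at peak frequency 1 Hz;
# scales as 1/f for any other row. Computed numerically from the window.
wavelet_efold_time <- function(type, f0) {
  fs_ref <- 64
  M <- 8192
  f <- (seq_len(M) - 1) / M * fs_ref
  h <- wavelet_window(f, type, f0)
  psi <- fft(h, inverse = TRUE) / M
  env <- Mod(psi)
  tt <- c(seq(0, M / 2 - 1), seq(-M / 2, -1)) / fs_ref
  thr <- max(env) / exp(1)
  max(abs(tt[env >= thr]))
}

#' Continuous wavelet transform on a logarithmic frequency grid
#'
#' Computes complex wavelet coefficients by frequency-domain multiplication
#' of the signal's Fourier transform with an analytic wavelet window at each
#' scale, with zero padding to the next power of two. The frequency grid is
#' log-spaced with `nv` voices per octave from `fmin` up to at most `fmax`.
#' Coefficients are amplitude-normalised: a unit-amplitude sinusoid at a grid
#' frequency yields `|coeff|` close to 1 on its row away from the edges.
#'
#' The cone of influence (COI) marks coefficients closer to a record edge
#' than twice the e-folding time of the wavelet envelope at that frequency
#' (the factor of two keeps the edge-induced amplitude bias of retained
#' coefficients below 1\%); COI coefficients are excluded from all time
#' averages downstream.
#'
#' @param x A [uniform_signal()].
#' @param fmin,fmax Transform frequency range in Hz (defaults 0.005-2).
#' @param nv Voices per octave (default 32, about 2.2\% grid spacing).
#' @param wavelet `"lognormal"` (default) or `"morlet"`.
#' @param f0 Central-frequency / resolution parameter (default 1).
#' @param preprocess Apply [preprocess_signal()] over `[fmin, fmax]` first
#'   (default `TRUE`).
#' @return A `wavelet_tfr` object: complex matrix `coeffs`
#'   (frequency x time), `freqs`, `times`, logical `coi_mask` (TRUE = edge
#'   affected), and `params`.
#' @export
cwt_tfr <- function(x, fmin = 0.005, fmax = 2, nv = 32,
                    wavelet = c("lognormal", "morlet"), f0 = 1,
                    preprocess = TRUE) {
  stopifnot(inherits(x, "uniform_signal"))
  wavelet <- match.arg(wavelet)
  if (fmax > x$fs / 2 + 1e-12) stop("fmax exceeds the Nyquist frequency")
  if (signal_duration(x) < 5 / fmin)
    warning("record shorter than 5 cycles at fmin; lowest frequencies are mostly inside the COI")
  if (preprocess) x <- preprocess_signal(x, fmin, fmax)
  n <- length(x$samples)
  te <- wavelet_efold_time(wavelet, f0)
  # zero padding must cover the wavelet tail at the lowest frequency; a
  # 5-smooth FFT length keeps the mixed-radix transform fast
  M <- stats::nextn(n + ceiling(te / fmin * x$fs), c(2, 3, 5))
  X <- fft(c(x$samples, numeric(M - n)))
  f <- (seq_len(M) - 1) / M * x$fs
  f[f > x$fs / 2] <- f[f > x$fs / 2] - x$fs    # signed frequencies
  K <- floor(nv * log2(fmax / fmin)) + 1L
  freqs <- fmin * 2^((seq_len(K) - 1) / nv)
  co <- matrix(0i, K, n)
  pos <- which(f > 0)
  lf <- log(f[pos])
  half <- sqrt(2 * log(1e16)) / (2 * pi * f0)  # window support, log-freq units
  for (k in seq_len(K)) {
    # windows are dilations of one mother: evaluate only on the support
    sel <- if (wavelet == "lognormal") {
      pos[abs(lf - log(freqs[k])) < half]
    } else {
      pos[abs(f[pos] / freqs[k] - 1) < half]
    }
    Y <- complex(M)
    # factor 2: analytic signal convention so |coeff| estimates amplitude
    Y[sel] <- X[sel] * (2 * wavelet_window(f[sel] / freqs[k], wavelet, f0))
    co[k, ] <- fft(Y, inverse = TRUE)[seq_len(n)] / M
  }
  tt <- signal_times(x)
  # COI rows have two contiguous edge blocks: samples closer to an edge than
  # twice the e-folding time te/f_k (the factor 2 keeps the amplitude bias
  # of retained coefficients below 1%; the wavelet envelope has slow time
  # tails, so the bias at exactly one e-folding time is still ~8%)
  coi <- matrix(FALSE, K, n)
  for (k in seq_len(K)) {
    mk <- floor(2 * te / freqs[k] * x$fs)
    if (mk >= 1) {
      mk <- min(mk, n)
      coi[k, c(seq_len(mk), seq.int(n - mk + 1L, n))] <- TRUE
    }
  }
  structure(list(coeffs = co, freqs = freqs, times = tt, coi_mask = coi,
                 params = list(wavelet_type = wavelet, f0 = f0, fmin = fmin,
                               fmax = fmax, nv = nv,
                               preprocess = preprocess, fs = x$fs,
                               efold_1hz = te)),
            class = "wavelet_tfr")
}

#' @export
print.wavelet_tfr <- function(x, ...) {
  cat(sprintf(
    "<wavelet_tfr> %d freqs x %d times; %s wavelet (f0 = %g), %g-%g Hz, %d voices/octave\n",
    length(x$freqs), length(x$times), x$params$wavelet_type, x$params$f0,
    x$params$fmin, x$params$fmax, x$params$nv))
  invisible(x)
}

#' Time-averaged wavelet power spectrum
#'
#' Squares the coefficient amplitudes and averages over time per frequency,
#' excluding cone-of-influence times.
#'
#' @param tfr A [cwt_tfr()] result.
#' @return A `ta_spectrum` object: `freqs`, `power` (NA where a frequency has
#'   no valid times), `n_valid`, and the source `params`.
#' @export
time_average_power <- function(tfr) {
  stopifnot(inherits(tfr, "wavelet_tfr"))
  p2 <- Mod(tfr$coeffs)^2
  p2[tfr$coi_mask] <- NA_real_
  n_valid <- rowSums(!tfr$coi_mask)
  power <- rowMeans(p2, na.rm = TRUE)
  power[n_valid == 0L] <- NA_real_
  structure(list(freqs = tfr$freqs, power = power, n_valid = n_valid,
                 params = tfr$params, normalised = FALSE),
            class = "ta_spectrum")
}

#' Normalise a time-averaged spectrum to unit log-frequency integral
#'
#' Divides the power by its sum over frequencies weighted by the (constant)
#' log-frequency bin width, so that `sum(power * dln f) = 1`. Normalised
#' spectra are invariant to amplitude rescaling of the input signal and can
#' be averaged across subjects.
#'
#' @param spec A `ta_spectrum`.
#' @return The normalised `ta_spectrum`.
#' @export
normalise_spectrum <- function(spec) {
  stopifnot(inherits(spec, "ta_spectrum"))
  dlnf <- log(2) / spec$params$nv
  tot <- sum(spec$power * dlnf, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) stop("cannot normalise an all-zero spectrum")
  spec$power <- spec$power / tot
  spec$normalised <- TRUE
  spec
}

#' Pointwise group mean of time-averaged spectra
#'
#' @param specs List of `ta_spectrum` objects on identical frequency grids.
#' @return A `ta_spectrum` with the pointwise mean power and an `n_spectra`
#'   field.
#' @export
group_mean_spectra <- function(specs) {
  stopifnot(length(specs) >= 1L)
  f0 <- specs[[1L]]$freqs
  for (s in specs)
    if (length(s$freqs) != length(f0) || any(abs(s$freqs - f0) > 1e-12 * f0))
      stop("spectra must share an identical frequency grid")
  P <- vapply(specs, function(s) s$power, numeric(length(f0)))
  out <- specs[[1L]]
  out$power <- rowMeans(matrix(P, nrow = length(f0)), na.rm = TRUE)
  out$n_spectra <- length(specs)
  out
}

#' Export a spectrum as TSV
#' @param spec A `ta_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  write.table(data.frame(freq = spec$freqs, power = spec$power), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
plot.ta_spectrum <- function(x, ...) {
  graphics::plot(x$freqs, x$power, type = "l", log = "x",
                 xlab = "Frequency (Hz)",
                 ylab = if (isTRUE(x$normalised)) "Normalised power" else "Power",
                 ...)
  invisible(x)
}
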