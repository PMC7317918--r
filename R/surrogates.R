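#' One IAAFT surrogate of a signal
#'
#' Iterative amplitude-adjusted Fourier transform surrogate: starting from a
#' random permutation of the samples, alternately (i) impose the original
#' Fourier amplitude spectrum while keeping the current phases and (ii)
#' rank-remap the result onto the original value distribution, until the
#' relative change of the amplitude-spectrum mismatch falls below `tol` or
#' `max_iter` is reached. The returned series is the rank-remapped one, so
#' its sorted values equal the original's sorted values exactly, while the
#' amplitude spectrum is preserved approximately. Any phase relation with a
#' simultaneously recorded signal is destroyed, which is exactly the null
#' needed for coherence significance testing.
#'
#' @param x A [uniform_signal()] or numeric vector, length >= 64.
#' @param seed Integer seed.
#' @param max_iter Maximum iterations (default 100).
#' @param tol Relative spectral-change stopping tolerance (default 1e-6).
#' @return A `surrogate` object: `samples`, `iterations_used`,
#'   `spectral_error` (final relative L2 amplitude-spectrum mismatch).
#' @export
iaaft <- function(x, seed = 1L, max_iter = 100L, tol = 1e-6) {
  s0 <- if (inherits(x, "uniform_signal")) x$samples else as.numeric(x)
  n <- length(s0)
  if (n < 64L) stop("IAAFT needs at least 64 samples")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (diff(range(s0)) == 0) stop("constant signal has no phase content")
  target_amp <- Mod(fft(s0))
  sorted <- sort(s0)
  s <- with_seed(seed, sample(s0))
  err_prev <- Inf
  it <- 0L
  err <- NA_real_
  repeat {
    it <- it + 1L
    ph <- Arg(fft(s))
    s2 <- Re(fft(target_amp * exp(1i * ph), inverse = TRUE)) / n
    s <- numeric(n)
    s[order(s2)] <- sorted                    # rank remap: exact distribution
    err <- sqrt(sum((Mod(fft(s)) - target_amp)^2) / sum(target_amp^2))
    if (it >= max_iter || abs(err_prev - err) <= tol * max(err, 1e-300)) break
    err_prev <- err
  }
  structure(list(samples = s, iterations_used = it, spectral_error = err),
            class = "surrogate")
}

#' Set of IAAFT surrogates
#'
#' Generates `n` independent surrogates from a master seed (child seed
#' `seed + i` for the i-th surrogate).
#'
#' @param x A [uniform_signal()] or numeric vector.
#' @param n Number of surrogates (default 100).
#' @param seed Master seed.
#' @param ... Passed to [iaaft()].
#' @return A `surrogate_set`: list with `surrogates` (list of sample
#'   vectors), `n`, `seed`, `iterations_used`, `spectral_error` (per
#'   surrogate).
#' @export
surrogate_set <- function(x, n = 100L, seed = 1L, ...) {
  stopifnot(n >= 1L)
  ss <- lapply(seq_len(n), function(i) iaaft(x, seed = seed + i, ...))
  structure(list(surrogates = lapply(ss, `[[`, "samples"), n = n, seed = seed,
                 iterations_used = vapply(ss, `[[`, integer(1),
                                          "iterations_used"),
                 spectral_error = vapply(ss, `[[`, numeric(1),
                                         "spectral_error")),
            class = "surrogate_set")
}

#' Per-frequency surrogate significance threshold for phase coherence
#'
#' Computes the raw wavelet phase coherence between `sig1` (left intact) and
#' `n` IAAFT surrogates of `sig2`, and returns the per-frequency 95th (by
#' default) percentile across surrogates, using the linear-interpolation
#' quantile. Surrogacy is one-sided: randomising one member of the pair is
#' enough to destroy their phase relation while preserving each signal's
#' spectrum and value distribution.
#'
#' @param sig1,sig2 [uniform_signal()]s of equal length and rate.
#' @param n Number of surrogates (default 100).
#' @param percentile Percentile in (0, 100) (default 95). A warning is
#'   issued when `n < 20` leaves the 95th percentile poorly resolved.
#' @param seed Master seed for the surrogate children.
#' @param max_iter,tol IAAFT stopping parameters, passed to [iaaft()].
#' @param ... Transform parameters passed to [cwt_tfr()] (e.g. `fmin`,
#'   `fmax`, `nv`, `wavelet`, `f0`).
#' @return A `coherence_threshold` object: `freqs`, `threshold`, `n`,
#'   `percentile`, `seed`.
#' @export
coherence_threshold <- function(sig1, sig2, n = 100L, percentile = 95,
                                seed = 1L, max_iter = 100L, tol = 1e-6, ...) {
  stopifnot(inherits(sig1, "uniform_signal"), inherits(sig2, "uniform_signal"))
  if (n < 20L && percentile >= 95)
    warning("n < 20 surrogates resolves the 95th percentile poorly")
  tfr1 <- cwt_tfr(sig1, ...)
  coh_rows <- matrix(NA_real_, n, length(tfr1$freqs))
  for (i in seq_len(n)) {
    su <- iaaft(sig2, seed = seed + i, max_iter = max_iter, tol = tol)
    ssig <- uniform_signal(su$samples, fs = sig2$fs, label = sig2$label,
                           t0 = sig2$t0)
    coh_rows[i, ] <- phase_coherence(tfr1, cwt_tfr(ssig, ...))$raw_coh
  }
  thr <- apply(coh_rows, 2, quantile, probs = percentile / 100,
               na.rm = TRUE, names = FALSE, type = 7)
  structure(list(freqs = tfr1$freqs, threshold = thr, n = n,
                 percentile = percentile, seed = seed),
            class = "coherence_threshold")
}

#' Subtract a surrogate threshold from a coherence spectrum
#'
#' Fills `adj_coh = raw_coh - threshold` (not clipped at zero: near-zero
#' adjusted values are informative and clipping would bias band means) and
#' the significance mask `raw_coh > threshold`.
#'
#' @param coh A `coherence_spectrum`.
#' @param threshold A `coherence_threshold` (or bare numeric vector on the
#'   same grid).
#' @return The updated `coherence_spectrum`.
#' @export
apply_threshold <- function(coh, threshold) {
  stopifnot(inherits(coh, "coherence_spectrum"))
  thr <- if (inherits(threshold, "coherence_threshold")) {
    if (length(threshold$freqs) != length(coh$freqs) ||
        any(abs(threshold$freqs - coh$freqs) > 1e-12 * coh$freqs))
      stop("threshold frequency grid does not match the coherence spectrum")
    threshold$threshold
  } else {
    if (length(threshold) != length(coh$freqs))
      stop("threshold length does not match the frequency grid")
    as.numeric(threshold)
  }
  coh$threshold <- thr
  coh$adj_coh <- coh$raw_coh - thr
  coh$significant <- coh$raw_coh > thr
  coh
}
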