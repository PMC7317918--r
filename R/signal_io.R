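#' Uniformly sampled physiological signal
#'
#' Lightweight container for one channel of a uniformly sampled recording
#' (ECG, respiratory effort, laser-Doppler flowmetry perfusion, or a derived
#' instantaneous-rate series). Samples are unit-free: LDF is in arbitrary
#' perfusion units and every downstream statistic (wavelet phase coherence,
#' band means, rank tests) is invariant to amplitude scaling.
#'
#' @param samples Numeric vector of samples; all values must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Channel name, one of `"ecg"`, `"resp"`, `"ldf_left"`,
#'   `"ldf_right"`, `"ihr"`, `"resp_rate"`, or any other identifier.
#' @param t0 Start time of the first sample in seconds (default 0).
#'
#' @return An object of class `uniform_signal`: a list with elements
#'   `samples`, `fs`, `label`, `t0`.
#' @examples
#' s <- uniform_signal(sin(2 * pi * 0.3 * seq(0, 60, by = 1 / 10)), fs = 10,
#'                     label = "resp")
#' signal_duration(s)
#' @export
uniform_signal <- function(samples, fs, label = "signal", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("uniform_signal needs at least 2 samples")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  if (!all(is.finite(samples)))
    stop("all samples must be finite; repair artefacts first")
  structure(list(samples = samples, fs = fs,
                 label = as.character(label)[1L], t0 = as.numeric(t0)[1L]),
            class = "uniform_signal")
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal '%s'> %d samples @ %g Hz (%.1f s, t0 = %g s)\n",
              x$label, length(x$samples), x$fs, signal_duration(x), x$t0))
  invisible(x)
}

#' Duration of a uniform signal in seconds
#' @param x A `uniform_signal`.
#' @return Duration `length(samples)/fs` in seconds.
#' @export
signal_duration <- function(x) length(x$samples) / x$fs

#' Time stamps of a uniform signal
#' @param x A `uniform_signal`.
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) x$t0 + (seq_along(x$samples) - 1) / x$fs

#' Artefact mask over a signal
#'
#' Half-open index intervals `[start, end)` (1-based start, exclusive end)
#' flagged as movement artefact. Intervals must be sorted, non-overlapping
#' and within the signal bounds they are applied to.
#'
#' @param intervals Two-column integer matrix (or empty) with columns
#'   `start`, `end`; rows are half-open index ranges `[start, end)`.
#' @return An `artefact_mask` object.
#' @export
artefact_mask <- function(intervals = matrix(integer(0), ncol = 2)) {
  intervals <- matrix(as.integer(intervals), ncol = 2)
  colnames(intervals) <- c("start", "end")
  if (nrow(intervals)) {
    if (any(intervals[, 2] <= intervals[, 1]))
      stop("artefact intervals must satisfy end > start")
    o <- order(intervals[, 1])
    intervals <- intervals[o, , drop = FALSE]
    if (nrow(intervals) > 1 &&
        any(intervals[-1, 1] < intervals[-nrow(intervals), 2]))
      stop("artefact intervals must be non-overlapping")
  }
  structure(list(intervals = intervals), class = "artefact_mask")
}

mask_logical <- function(mask, n) {
  flag <- logical(n)
  iv <- mask$intervals
  if (nrow(iv)) {
    if (any(iv[, 1] < 1L) || any(iv[, 2] > n + 1L))
      stop("artefact mask exceeds signal bounds")
    for (r in seq_len(nrow(iv))) flag[iv[r, 1]:(iv[r, 2] - 1L)] <- TRUE
  }
  flag
}

runs_to_intervals <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  artefact_mask(cbind(starts[keep], ends[keep] + 1L))
}

#' Read multichannel signals from the TSV dialect
#'
#' The dialect is UTF-8 tab-separated text with a header row
#' `time<TAB>label1<TAB>...` and one column per channel; time in seconds with
#' decimal point. The sampling rate is inferred from the time column, which
#' must be uniform to within a relative tolerance of 1e-6 of the mean step.
#'
#' @param path Path to the TSV file.
#' @return A named list of [uniform_signal()] objects, one per channel column.
#' @export
read_signals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "time")
    stop("format error: expected header 'time<TAB>label1<TAB>...'")
  tt <- as.numeric(df[["time"]])
  if (length(tt) < 2L) stop("format error: need at least 2 rows")
  dt <- diff(tt)
  dt0 <- mean(dt)
  if (dt0 <= 0 || any(abs(dt - dt0) > 1e-6 * abs(dt0)))
    stop("format error: non-uniform time grid (relative jitter > 1e-6)")
  fs <- 1 / dt0
  chans <- names(df)[-1L]
  out <- lapply(chans, function(ch)
    uniform_signal(df[[ch]], fs = fs, label = ch, t0 = tt[1L]))
  names(out) <- chans
  out
}

#' Write signals to the TSV dialect
#'
#' Inverse of [read_signals()]: all signals must share `fs`, `t0` and length.
#' Values are written with full double precision so that a read round-trip
#' reproduces the samples exactly.
#'
#' @param signals Named list of [uniform_signal()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(signals, path) {
  stopifnot(length(signals) >= 1L)
  fs <- signals[[1L]]$fs
  n <- length(signals[[1L]]$samples)
  t0 <- signals[[1L]]$t0
  for (s in signals)
    if (s$fs != fs || length(s$samples) != n || s$t0 != t0)
      stop("all signals must share fs, length and t0")
  # 17 significant digits round-trips doubles exactly through decimal text
  df <- data.frame(time = sprintf("%.17g", t0 + (seq_len(n) - 1) / fs))
  labs <- vapply(signals, function(s) s$label, character(1))
  for (i in seq_along(signals))
    df[[labs[i]]] <- sprintf("%.17g", signals[[i]]$samples)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Downsample a signal with anti-aliasing
#'
#' Applies a linear-phase low-pass FIR filter with cutoff `0.45 * target_fs`
#' (Blackman-windowed design, about 74 dB stopband attenuation) and then
#' decimates by the integer factor `fs / target_fs`. Linear phase preserves
#' the relative timing of R peaks and respiratory events; the group delay is
#' compensated exactly. Only downsampling by an integer factor is supported
#' (e.g. the 1200 Hz ECG/respiration recordings to the 40 Hz working rate,
#' factor 30).
#'
#' @param x A [uniform_signal()].
#' @param target_fs Target sampling rate in Hz; must divide `x$fs`.
#' @return The downsampled `uniform_signal`.
#' @export
resample_signal <- function(x, target_fs) {
  stopifnot(inherits(x, "uniform_signal"))
  if (target_fs > x$fs) stop("upsampling is not supported (target_fs > fs)")
  if (isTRUE(all.equal(target_fs, x$fs))) return(x)
  q <- x$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop("fs / target_fs must be an integer decimation factor")
  q <- as.integer(round(q))
  cutoff <- 0.45 * target_fs
  trans <- 0.05 * target_fs                   # to the new Nyquist at 0.5*target_fs
  ntaps <- ceiling(5.5 * x$fs / trans)        # Blackman transition ~5.5/N * fs
  ntaps <- ntaps + (ntaps %% 2L)              # even order -> odd tap count, type I
  h <- signal::fir1(ntaps, cutoff / (x$fs / 2), type = "low",
                    window = signal::blackman(ntaps + 1))
  y <- fir_filter_zero_phase(x$samples, h)
  idx <- seq(1L, length(y), by = q)
  uniform_signal(y[idx], fs = target_fs, label = x$label, t0 = x$t0)
}

# Linear-phase FIR via FFT convolution, group delay (ntaps/2 samples) removed.
# Edges are padded by reflection so filtered length equals input length.
fir_filter_zero_phase <- function(x, h) {
  n <- length(x)
  m <- length(h)
  half <- (m - 1L) %/% 2L
  pad <- pmin(half, n - 1L)
  xe <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  L <- stats::nextn(length(xe) + m - 1L, 2)
  Y <- fft(c(xe, numeric(L - length(xe)))) * fft(c(h, numeric(L - m)))
  y <- Re(fft(Y, inverse = TRUE)) / L
  y[(pad + half + 1L):(pad + half + n)]
}

#' Repair flagged movement artefacts by linear interpolation
#'
#' Samples inside each masked interval are replaced by linear interpolation
#' between the nearest unmasked neighbours; intervals touching a signal
#' boundary are replaced by constant extension of the nearest unmasked
#' sample. All unmasked samples are returned bit-exactly unchanged.
#'
#' @param x A [uniform_signal()].
#' @param mask An [artefact_mask()] valid for `x`.
#' @return The repaired `uniform_signal`.
#' @export
repair_artefacts <- function(x, mask) {
  stopifnot(inherits(x, "uniform_signal"), inherits(mask, "artefact_mask"))
  flag <- mask_logical(mask, length(x$samples))
  if (!any(flag)) return(x)
  if (all(flag)) stop("cannot repair a fully masked signal")
  s <- x$samples
  good <- which(!flag)
  s[flag] <- approx(x = good, y = s[good], xout = which(flag),
                    method = "linear", rule = 2)$y
  uniform_signal(s, fs = x$fs, label = x$label, t0 = x$t0)
}

#' Detect movement artefacts by robust z-score
#'
#' Flags samples whose robust z-score, `(x - median) / (1.4826 * MAD)`,
#' exceeds `z_thresh` in absolute value, then dilates each flagged run by
#' 0.25 s on both sides. Intended as an optional automatic stand-in for
#' visual artefact marking; masks can equally be supplied from a sidecar
#' file via [read_artefact_mask()].
#'
#' @param x A [uniform_signal()].
#' @param z_thresh Positive threshold in robust SD units (default 6).
#' @return An [artefact_mask()]; empty for a constant signal (MAD = 0).
#' @export
detect_artefacts <- function(x, z_thresh = 6) {
  stopifnot(inherits(x, "uniform_signal"), z_thresh > 0)
  m <- median(x$samples)
  md <- mad(x$samples)
  if (md == 0) return(artefact_mask())
  flag <- abs(x$samples - m) / md > z_thresh
  if (!any(flag)) return(artefact_mask())
  w <- as.integer(round(0.25 * x$fs))
  if (w > 0) {
    idx <- which(flag)
    lo <- pmax(1L, idx - w); hi <- pmin(length(flag), idx + w)
    for (i in seq_along(idx)) flag[lo[i]:hi[i]] <- TRUE
  }
  runs_to_intervals(flag)
}

#' Read an artefact-mask sidecar file
#'
#' Sidecar format: TSV with columns `label`, `start_s`, `end_s` (seconds,
#' half-open). Returns the mask for one channel converted to sample indices.
#'
#' @param path Sidecar TSV path.
#' @param signal The [uniform_signal()] the mask applies to (for `fs`/`t0`).
#' @return An [artefact_mask()].
#' @export
read_artefact_mask <- function(path, signal) {
  df <- read.delim(path)
  stopifnot(all(c("label", "start_s", "end_s") %in% names(df)))
  df <- df[df$label == signal$label, , drop = FALSE]
  if (!nrow(df)) return(artefact_mask())
  start <- pmax(1L, as.integer(floor((df$start_s - signal$t0) * signal$fs)) + 1L)
  end <- pmin(length(signal$samples) + 1L,
              as.integer(ceiling((df$end_s - signal$t0) * signal$fs)) + 1L)
  artefact_mask(cbind(start, end))
}
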