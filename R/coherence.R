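#' Wavelet phase coherence between two transforms
#'
#' For each frequency `f_k`, forms the phase difference
#' `dPhi[k, n] = Phi2[k, n] - Phi1[k, n]` over jointly valid times (outside
#' both cones of influence and with nonzero amplitude in both transforms)
#' and computes
#' `C(f_k) = sqrt(<cos dPhi>^2 + <sin dPhi>^2)`,
#' the magnitude of the time-averaged unit phasor: 1 when the phase
#' difference is constant over time, near 0 when it drifts monotonically.
#' The circular mean phase difference `atan2(<sin>, <cos>)` is returned per
#' frequency.
#'
#' The convention is `Phi2 - Phi1`: in the cardiorespiratory call the first
#' argument is the instantaneous heart rate and the second the respiration,
#' so a positive phase difference means respiration leads.
#'
#' @param tfr1,tfr2 [cwt_tfr()] results on identical frequency and time
#'   grids.
#' @return A `coherence_spectrum`: `freqs`, `raw_coh`, `phase_diff`,
#'   `n_valid`, plus `threshold`/`adj_coh`/`significant` slots filled by
#'   [apply_threshold()] (NA until then).
#' @export
phase_coherence <- function(tfr1, tfr2) {
  stopifnot(inherits(tfr1, "wavelet_tfr"), inherits(tfr2, "wavelet_tfr"))
  if (length(tfr1$freqs) != length(tfr2$freqs) ||
      any(abs(tfr1$freqs - tfr2$freqs) > 1e-12 * tfr1$freqs) ||
      length(tfr1$times) != length(tfr2$times))
    stop("transforms must share identical frequency and time grids")
  cc <- coherence_rows(tfr1$coeffs, tfr2$coeffs,
                       tfr1$coi_mask, tfr2$coi_mask)
  n_valid <- cc$n_valid
  raw <- Mod(cc$mean_u)
  phd <- Arg(cc$mean_u)
  raw[n_valid == 0L] <- NA_real_
  phd[n_valid == 0L] <- NA_real_
  structure(list(freqs = tfr1$freqs, raw_coh = raw,
                 threshold = rep(NA_real_, length(raw)),
                 adj_coh = rep(NA_real_, length(raw)),
                 significant = rep(NA, length(raw)),
                 phase_diff = phd, n_valid = n_valid,
                 params = tfr1$params,
                 convention = "phase_diff = Phi(arg2) - Phi(arg1)"),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf(
    "<coherence_spectrum> %d freqs (%g-%g Hz); max raw coherence %.3f at %.4g Hz%s\n",
    length(x$freqs), min(x$freqs), max(x$freqs),
    max(x$raw_coh, na.rm = TRUE),
    x$freqs[which.max(x$raw_coh)],
    if (all(is.na(x$threshold))) " (no surrogate threshold yet)" else
      " (threshold-adjusted)"))
  invisible(x)
}

#' Band-averaged coherence statistic
#'
#' Unweighted mean of the (threshold-adjusted, by default) coherence over
#' the grid frequencies inside the closed band. The 0.03-0.15 Hz modulation
#' band summarises periodic breathing as a single value per
#' subject-condition pair.
#'
#' @param coh A `coherence_spectrum`.
#' @param f_lo,f_hi Band edges in Hz (defaults 0.03 and 0.15).
#' @param use `"adjusted"` (default; requires [apply_threshold()] first) or
#'   `"raw"`.
#' @return Scalar band mean.
#' @export
band_mean <- function(coh, f_lo = 0.03, f_hi = 0.15,
                      use = c("adjusted", "raw")) {
  stopifnot(inherits(coh, "coherence_spectrum"))
  use <- match.arg(use)
  sel <- coh$freqs >= f_lo & coh$freqs <= f_hi
  if (!any(sel)) stop("band contains no grid frequencies")
  v <- if (use == "adjusted") coh$adj_coh[sel] else coh$raw_coh[sel]
  if (use == "adjusted" && all(is.na(v)))
    stop("no adjusted coherence; run apply_threshold() first or use = 'raw'")
  mean(v, na.rm = TRUE)
}

#' Lead/lag classification from a phase difference
#'
#' Interprets the circular mean phase difference at one frequency under the
#' fixed convention `Phi2 - Phi1` (signal 1 = IHR, signal 2 = respiration in
#' the cardiorespiratory call): positive means signal 2 (respiration) leads.
#' Differences smaller than `tol` in absolute value are classified as
#' in-phase.
#'
#' @param phase_diff Phase difference in radians at the frequency of
#'   interest.
#' @param tol In-phase tolerance in radians (default 0.1).
#' @return `"signal2_leads"`, `"signal1_leads"`, or `"in_phase"`.
#' @export
lead_lag <- function(phase_diff, tol = 0.1) {
  stopifnot(is.finite(phase_diff))
  if (abs(phase_diff) < tol) "in_phase"
  else if (phase_diff > 0) "signal2_leads"
  else "signal1_leads"
}

#' Export a coherence spectrum as TSV
#' @param coh A `coherence_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coherence <- function(coh, path) {
  write.table(data.frame(freq = coh$freqs, raw = coh$raw_coh,
                         threshold = coh$threshold, adjusted = coh$adj_coh,
                         phase_diff = coh$phase_diff),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
plot.coherence_spectrum <- function(x, ...) {
  graphics::plot(x$freqs, x$raw_coh, type = "l", log = "x", ylim = c(0, 1),
                 xlab = "Frequency (Hz)", ylab = "Phase coherence", ...)
  if (!all(is.na(x$threshold)))
    graphics::lines(x$freqs, x$threshold, lty = 2)
  invisible(x)
}
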