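#' Configuration for the synthetic cardiorespiratory generator
#'
#' Defines one subject-condition recording with the oscillatory structure the
#' analysis pipeline assumes: respiration near 0.3 Hz whose amplitude is
#' modulated at the periodic-breathing (PB) frequency near 0.058 Hz with
#' optional apnoea epochs; heart rate near 1 Hz modulated both at the
#' respiration frequency (respiratory sinus arrhythmia, RSA) and at the PB
#' frequency; and skin-perfusion (LDF) signals carrying cardiac, respiratory
#' and low-frequency vasomotion components plus a PB-locked component.
#'
#' A pure amplitude-modulated carrier has no spectral line at the modulation
#' frequency itself (only sidebands at `f_resp +/- f_mod`); observed hypoxic
#' respiration spectra show a genuine low-frequency peak, so the generator
#' adds an explicit baseline component `b_base` at `f_mod` representing the
#' slow drift of thoracic volume across hyperpnoea/apnoea cycles.
#'
#' @param f_resp Respiration carrier frequency in Hz (default 0.30, the
#'   approximate hypoxic respiration rate).
#' @param f_mod PB modulation frequency in Hz (default 0.058).
#' @param f_heart Baseline heart rate in Hz (default 1.0).
#' @param m_pb PB amplitude-modulation depth of respiration, in `[0, 1]`.
#' @param a_rsa RSA frequency-modulation depth of the heart rate, Hz.
#' @param a_pb_hr Heart-rate modulation depth at the PB frequency, Hz.
#' @param b_base Amplitude of the explicit respiration baseline component at
#'   `f_mod` (same arbitrary units as the carrier).
#' @param apnoea_duty Fraction of each PB cycle spent at near-zero breathing
#'   amplitude, in `[0, 1)`.
#' @param phi_lag Phase lag (radians) of the heart-rate PB component behind
#'   the respiration PB envelope.
#' @param a_lf Depth (Hz) of the heart rate's intrinsic low-frequency
#'   variability: an independent phase-diffusing oscillator wandering in
#'   0.04-0.15 Hz (the Mayer-wave / baroreflex band), present in every
#'   condition. It competes with the PB component at `f_mod`, so
#'   cardiorespiratory coherence grades with PB depth instead of
#'   saturating.
#' @param b_lf Amplitude of the analogous independent low-frequency
#'   baseline variability of the respiration channel.
#' @param noise_sd Additive white-noise SD per channel.
#' @param duration_s Record duration in seconds (default 1800, i.e. 30 min).
#' @param fs Sampling rate in Hz (default 40, the working rate).
#' @param freq_jitter_sd SD of the bounded random walk of the instantaneous
#'   frequencies, in Hz per sqrt(second); makes coherence of coupled pairs
#'   fall below 1 while remaining well above 0, as for real signals.
#' @param seed Integer seed; every draw is reproducible from it.
#'
#' @return A `synthetic_config` list with the above fields validated.
#' @export
synthetic_config <- function(f_resp = 0.30, f_mod = 0.058, f_heart = 1.0,
                             m_pb = 0.5, a_rsa = 0.05, a_pb_hr = 0.05,
                             b_base = 0.3, apnoea_duty = 0.25, phi_lag = 0.3,
                             a_lf = 0.015, b_lf = 0.075,
                             noise_sd = 0.1, duration_s = 1800, fs = 40,
                             freq_jitter_sd = 0.001, seed = 1L) {
  cfg <- list(f_resp = f_resp, f_mod = f_mod, f_heart = f_heart, m_pb = m_pb,
              a_rsa = a_rsa, a_pb_hr = a_pb_hr, b_base = b_base,
              apnoea_duty = apnoea_duty, phi_lag = phi_lag,
              a_lf = a_lf, b_lf = b_lf,
              noise_sd = noise_sd, duration_s = duration_s, fs = fs,
              freq_jitter_sd = freq_jitter_sd, seed = as.integer(seed))
  with(cfg, {
    stopifnot(f_resp > 0, f_mod > 0, f_heart > 0, fs > 0, duration_s > 0)
    if (!(f_mod < f_resp && f_resp < f_heart))
      stop("frequencies must satisfy f_mod < f_resp < f_heart")
    if (m_pb < 0 || m_pb > 1) stop("m_pb must lie in [0, 1]")
    if (apnoea_duty < 0 || apnoea_duty >= 1)
      stop("apnoea_duty must lie in [0, 1)")
    if (duration_s * f_mod < 10)
      stop("duration_s * f_mod must be >= 10 (enough PB cycles for coherence)")
  })
  structure(cfg, class = "synthetic_config")
}

# Restore the caller's RNG state after seeded generation.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Mean-reverting (Ornstein-Uhlenbeck) frequency process: relaxation time
# tau (s), stationary SD sd_st. The stationary law is Gaussian centred on
# `mean`, so long-run spectral peaks sit at `mean` by construction.
ou_process <- function(n, mean, tau, sd_st, dt) {
  sd_noise <- sd_st * sqrt(2 * dt / tau)
  eps <- rnorm(n - 1L, 0, sd_noise)
  f <- numeric(n)
  f[1L] <- mean + rnorm(1L, 0, sd_st)
  a <- dt / tau
  for (i in seq_len(n - 1L)) f[i + 1L] <- f[i] + (mean - f[i]) * a + eps[i]
  f
}

# Bounded random walk: increments N(0, sd_per_sqrt_s * sqrt(dt)), reflected
# at [lo, hi]. Deterministic given the RNG state.
bounded_walk <- function(n, start, sd_step, lo, hi) {
  w <- cumsum(c(start, rnorm(n - 1L, 0, sd_step)))
  # reflect into [lo, hi] (twice is enough for small steps)
  for (k in 1:2) {
    w <- ifelse(w > hi, 2 * hi - w, w)
    w <- ifelse(w < lo, 2 * lo - w, w)
  }
  pmin(pmax(w, lo), hi)
}

# Shared latent state: respiration frequency walk and PB envelope, so the
# respiration, heart and LDF channels of one record are mutually coupled.
synth_latent <- function(cfg) {
  n <- as.integer(round(cfg$duration_s * cfg$fs))
  dt <- 1 / cfg$fs
  with_seed(cfg$seed, {
    f_r <- bounded_walk(n, cfg$f_resp, cfg$freq_jitter_sd * sqrt(dt),
                        0.145, 0.6)
    jit_h <- bounded_walk(n, 0, cfg$freq_jitter_sd * sqrt(dt), -0.1, 0.1)
    # the PB rhythm itself drifts slightly, as in real periodic breathing;
    # the drifting phase is shared by the respiration envelope, the
    # baseline component and the heart-rate PB component, so cross-signal
    # phase locking is preserved while the spectral line is spread over
    # many Fourier bins (which is what lets IAAFT surrogates destroy the
    # phase relation). Mean reversion (OU, tau 60 s, stationary SD 4% of
    # f_mod) pins the long-run spectral peak at f_mod itself
    f_pb <- ou_process(n, cfg$f_mod, tau = 60, sd_st = 0.04 * cfg$f_mod,
                       dt = dt)
    t <- (seq_len(n) - 1) * dt
    phase_resp <- 2 * pi * cumsum(f_r) * dt
    phase_pb <- 2 * pi * cumsum(f_pb) * dt
    # envelope: (1-m) + m * max(0, cos(phase_pb) - c)/(1-c),
    # c set so the sub-threshold (apnoea) fraction of each cycle = duty
    cth <- cos(pi * (1 - cfg$apnoea_duty))
    env_raw <- pmax(0, cos(phase_pb) - cth) / (1 - cth)
    env <- (1 - cfg$m_pb) + cfg$m_pb * env_raw
    list(n = n, t = t, dt = dt, f_r = f_r, phase_resp = phase_resp,
         phase_pb = phase_pb, env = env, jit_h = jit_h)
  })
}

# Independent low-frequency oscillator phase: frequency wanders in the
# 0.04-0.15 Hz band (random walk, SD 0.001 Hz per sqrt(s)), random initial
# phase. Channel-specific seed offsets keep the oscillators independent.
lf_phase <- function(cfg, n, dt, seed_offset) {
  with_seed(cfg$seed + seed_offset, {
    f_lf <- bounded_walk(n, runif(1, 0.06, 0.13), 0.001 * sqrt(dt),
                         0.04, 0.15)
    2 * pi * cumsum(f_lf) * dt + runif(1, 0, 2 * pi)
  })
}

#' Generate a synthetic respiration signal
#'
#' `resp(t) = E(t) sin(2 pi int f_resp dt) + b_base cos(2 pi f_mod t) + noise`
#' where the envelope `E(t)` implements PB amplitude modulation with apnoea
#' epochs and the carrier frequency performs a bounded random walk within the
#' respiration band 0.145-0.6 Hz.
#'
#' @param cfg A [synthetic_config()].
#' @return A [uniform_signal()] labelled `"resp"`.
#' @export
generate_respiration <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  lat <- synth_latent(cfg)
  noise <- with_seed(cfg$seed + 1003L, rnorm(lat$n, 0, cfg$noise_sd))
  x <- lat$env * sin(lat$phase_resp) +
    cfg$b_base * cos(lat$phase_pb) +
    cfg$b_lf * sin(lf_phase(cfg, lat$n, lat$dt, 1001L)) + noise
  uniform_signal(x, fs = cfg$fs, label = "resp")
}

#' Generate synthetic instantaneous heart rate and ECG
#'
#' The instantaneous heart rate is
#' `f_h(t) = f_heart + a_rsa sin(phase_resp) + a_pb_hr cos(2 pi f_mod t - phi_lag) + jitter`,
#' clipped to the cardiac band 0.5-2 Hz (a warning is issued if clipping acts
#' on more than 1\% of samples). The ECG is a train of unit-amplitude
#' Gaussian pulses (SD 20 ms) at beat times satisfying
#' `int_{t_i}^{t_{i+1}} f_h dt = 1`, plus additive noise.
#'
#' @param cfg A [synthetic_config()].
#' @param with_ecg Synthesise the pulse-train ECG as well (default `TRUE`);
#'   set `FALSE` when only the rate series is needed.
#' @return A list with elements `ihr` and (when requested) `ecg`, both
#'   [uniform_signal()]s.
#' @export
generate_heart <- function(cfg, with_ecg = TRUE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  lat <- synth_latent(cfg)
  f_h <- cfg$f_heart + cfg$a_rsa * sin(lat$phase_resp) +
    cfg$a_pb_hr * cos(lat$phase_pb - cfg$phi_lag) +
    cfg$a_lf * sin(lf_phase(cfg, lat$n, lat$dt, 2001L)) + lat$jit_h
  clipped <- f_h < 0.5 | f_h > 2
  if (mean(clipped) > 0.01)
    warning(sprintf("heart rate clipped to [0.5, 2] Hz for %.1f%% of samples",
                    100 * mean(clipped)))
  f_h <- pmin(pmax(f_h, 0.5), 2)
  ihr <- uniform_signal(f_h, fs = cfg$fs, label = "ihr")
  if (!with_ecg) return(list(ihr = ihr))
  # beat times: cardiac phase crosses successive integers
  cphase <- cumsum(f_h) * lat$dt
  beats <- approx(x = cphase, y = lat$t, xout = seq(1, floor(max(cphase))),
                  ties = "ordered")$y
  beats <- beats[is.finite(beats)]
  ecg_clean <- numeric(lat$n)
  sd_p <- 0.020
  w <- as.integer(ceiling(4 * sd_p * cfg$fs))
  for (tb in beats) {
    i0 <- as.integer(round(tb * cfg$fs)) + 1L
    idx <- max(1L, i0 - w):min(lat$n, i0 + w)
    ecg_clean[idx] <- ecg_clean[idx] + exp(-((lat$t[idx] - tb)^2) / (2 * sd_p^2))
  }
  noise <- with_seed(cfg$seed + 2003L, rnorm(lat$n, 0, cfg$noise_sd))
  ecg <- uniform_signal(ecg_clean + noise, fs = cfg$fs, label = "ecg")
  list(ihr = ihr, ecg = ecg)
}

#' Generate a synthetic laser-Doppler flowmetry (LDF) signal
#'
#' Sum of narrowband, phase-diffusing oscillators centred in the cardiac,
#' respiratory, myogenic (0.052-0.145 Hz), neurogenic (0.021-0.052 Hz) and
#' endothelial (0.005-0.021 Hz) intervals, plus a component at the PB
#' modulation frequency phase-locked to the respiration PB envelope with a
#' configurable lag, plus white noise. Amplitudes are arbitrary perfusion
#' units.
#'
#' @param cfg A [synthetic_config()].
#' @param amplitudes Named numeric vector of component amplitudes with names
#'   `cardiac`, `respiratory`, `myogenic`, `neurogenic`, `endothelial`, `pb`.
#' @param pb_lag Phase lag (radians) of the LDF PB component behind the
#'   respiration PB envelope (default 0: near-zero lag).
#' @param label Channel label (default `"ldf_left"`).
#' @return A [uniform_signal()].
#' @export
generate_ldf <- function(cfg,
                         amplitudes = c(cardiac = 0.3, respiratory = 0.5,
                                        myogenic = 0.4, neurogenic = 0.4,
                                        endothelial = 0.3, pb = 0.5),
                         pb_lag = 0, label = "ldf_left") {
  stopifnot(inherits(cfg, "synthetic_config"))
  lat <- synth_latent(cfg)
  centres <- c(myogenic = sqrt(0.052 * 0.145),
               neurogenic = sqrt(0.021 * 0.052),
               endothelial = sqrt(0.005 * 0.021))
  x <- with_seed(cfg$seed + 3003L, {
    out <- numeric(lat$n)
    # cardiac and respiratory components ride on the shared latent phases
    f_h <- cfg$f_heart + lat$jit_h
    out <- out + amplitudes[["cardiac"]] * sin(2 * pi * cumsum(f_h) * lat$dt +
                                                 runif(1, 0, 2 * pi))
    out <- out + amplitudes[["respiratory"]] * sin(lat$phase_resp +
                                                     runif(1, 0, 2 * pi))
    for (b in names(centres)) {
      # phase diffusion: frequency walks within the band
      fb <- bounded_walk(lat$n, centres[[b]], 0.1 * centres[[b]] * sqrt(lat$dt),
                         centres[[b]] / 1.5, centres[[b]] * 1.5)
      out <- out + amplitudes[[b]] * sin(2 * pi * cumsum(fb) * lat$dt +
                                           runif(1, 0, 2 * pi))
    }
    out + amplitudes[["pb"]] * cos(lat$phase_pb - pb_lag) +
      rnorm(lat$n, 0, cfg$noise_sd)
  })
  uniform_signal(x, fs = cfg$fs, label = label)
}

#' One subject-condition recording bundle
#'
#' @param subject_id Subject identifier.
#' @param condition One of `"NN"`, `"NHa"`, `"NH"`, `"HHa"`, `"HH"`
#'   (normobaric normoxia; acute/6-h normobaric hypoxia; acute/6-h hypobaric
#'   hypoxia).
#' @param signals Named list of [uniform_signal()]s sharing duration to
#'   within one sample.
#' @param genotypes Named character vector, gene -> genotype code
#'   (`NOTCH4` in GG/GA/AA, `CAT` in CC/CT/TT, similarly SOD2/BDNF/GPX1).
#' @return A `subject_record` object.
#' @export
subject_record <- function(subject_id, condition, signals, genotypes) {
  condition <- match.arg(condition, c("NN", "NHa", "NH", "HHa", "HH"))
  durs <- vapply(signals, signal_duration, numeric(1))
  steps <- vapply(signals, function(s) 1 / s$fs, numeric(1))
  if (diff(range(durs)) > max(steps))
    stop("all signals in a record must share duration to within one sample")
  vocab <- list(NOTCH4 = c("GG", "GA", "AA"), CAT = c("CC", "CT", "TT"),
                SOD2 = c("CC", "CT", "TT"), BDNF = c("GG", "GA", "AA"),
                GPX1 = c("CC", "CT", "TT"))
  for (g in names(genotypes))
    if (g %in% names(vocab) && !(genotypes[[g]] %in% vocab[[g]]))
      stop(sprintf("invalid %s code '%s'", g, genotypes[[g]]))
  structure(list(subject_id = subject_id, condition = condition,
                 signals = signals, genotypes = genotypes),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s / %s: channels %s\n", x$subject_id,
              x$condition, paste(names(x$signals), collapse = ", ")))
  invisible(x)
}

condition_profiles <- function() {
  # per-condition PB depth / PB heart-rate modulation / baseline shifts;
  # normoxia has essentially no PB, acute normobaric hypoxia weak PB,
  # sustained and hypobaric hypoxia pronounced PB with faster breathing and
  # elevated heart rate
  list(
    NN  = list(m_pb = 0, a_pb_hr = 0, b_base = 0, f_resp = 0.25,
               f_heart = 1.00, hypoxic = FALSE),
    NHa = list(m_pb = 0.15, a_pb_hr = 0.015, b_base = 0.10, f_resp = 0.26,
               f_heart = 1.02, hypoxic = TRUE),
    NH  = list(m_pb = 0.50, a_pb_hr = 0.050, b_base = 0.30, f_resp = 0.30,
               f_heart = 1.12, hypoxic = TRUE),
    HHa = list(m_pb = 0.50, a_pb_hr = 0.050, b_base = 0.30, f_resp = 0.28,
               f_heart = 1.05, hypoxic = TRUE),
    HH  = list(m_pb = 0.50, a_pb_hr = 0.050, b_base = 0.30, f_resp = 0.30,
               f_heart = 1.12, hypoxic = TRUE))
}

# Quota (fixed-margin) genotype sampling: per gene, group counts are set by
# largest-remainder rounding of n * freq and codes are randomly permuted
# across subjects. Conditioning on the margins emulates an observed cohort
# panel and avoids degenerate (near-empty) genotype groups in small cohorts.
# Default frequencies are the 22-subject study panel's empirical ones.
draw_genotypes <- function(n, genotype_freqs) {
  defaults <- list(NOTCH4 = c(GG = 7, GA = 12, AA = 3) / 22,
                   CAT = c(CC = 10, CT = 11, TT = 1) / 22,
                   SOD2 = c(CC = 0.35, CT = 0.45, TT = 0.20),
                   BDNF = c(GG = 0.65, GA = 0.30, AA = 0.05),
                   GPX1 = c(CC = 0.50, CT = 0.40, TT = 0.10))
  freqs <- utils::modifyList(defaults, as.list(genotype_freqs))
  out <- lapply(seq_len(n), function(i) character(0))
  for (g in names(freqs)) {
    p <- freqs[[g]]
    if (abs(sum(p) - 1) > 1e-8) stop("genotype frequencies must sum to 1: ", g)
    cnt <- floor(n * p)
    rem <- n * p - cnt
    short <- n - sum(cnt)
    if (short > 0) {
      add <- order(rem, decreasing = TRUE)[seq_len(short)]
      cnt[add] <- cnt[add] + 1L
    }
    codes <- sample(rep(names(p), cnt))
    for (i in seq_len(n)) out[[i]][g] <- codes[i]
  }
  out
}

#' Generate a synthetic cohort of subject-condition recordings
#'
#' Genotypes are drawn once per subject and shared across conditions. PB
#' depth (`m_pb`) and PB heart-rate modulation (`a_pb_hr`) follow the
#' per-condition profile (near zero in NN, small in NHa, large in NH, HHa and
#' HH), then are scaled up by `effect_sizes[["NOTCH4"]]` for NOTCH4 carriers
#' (GA/AA) in hypoxic conditions and scaled down by `effect_sizes[["CAT"]]`
#' for CAT carriers (CT/TT) in the hypobaric conditions (HHa/HH) only.
#' Resulting depths outside `[0, 1]` are clipped with a warning. Fully
#' reproducible from `seed`.
#'
#' @param n_subjects Number of subjects (default 22).
#' @param conditions Character vector of conditions to simulate.
#' @param genotype_freqs Named list, gene -> named probability vector over
#'   codes; genes not named keep default frequencies.
#' @param effect_sizes Named numeric: multiplicative PB-depth effects, e.g.
#'   `c(NOTCH4 = 1.5, CAT = 1.5)`; 1 means no effect.
#' @param seed Integer master seed.
#' @param base_cfg A [synthetic_config()] supplying duration, fs, noise and
#'   the remaining parameters common to all records.
#' @param channels Channels to synthesise per record; any of
#'   `"resp"`, `"ihr"`, `"ecg"`, `"ldf_left"`, `"ldf_right"`.
#' @return List of [subject_record()]s, one per subject-condition pair.
#' @export
generate_cohort <- function(n_subjects = 22,
                            conditions = c("NN", "NHa", "NH", "HHa", "HH"),
                            genotype_freqs = list(),
                            effect_sizes = c(NOTCH4 = 1.5, CAT = 1.5),
                            seed = 1L,
                            base_cfg = synthetic_config(),
                            channels = c("resp", "ihr")) {
  profiles <- condition_profiles()
  stopifnot(all(conditions %in% names(profiles)))
  channels <- match.arg(channels, c("resp", "ihr", "ecg", "ldf_left",
                                    "ldf_right"), several.ok = TRUE)
  genos <- with_seed(seed, draw_genotypes(n_subjects, genotype_freqs))
  subj_fh <- with_seed(seed + 1L, rnorm(n_subjects, 0, 0.04))
  records <- list()
  clip_warned <- FALSE
  for (i in seq_len(n_subjects)) {
    for (cond in conditions) {
      pr <- profiles[[cond]]
      m_pb <- pr$m_pb
      a_pb <- pr$a_pb_hr
      if (pr$hypoxic && genos[[i]][["NOTCH4"]] %in% c("GA", "AA")) {
        m_pb <- m_pb * effect_sizes[["NOTCH4"]]
        a_pb <- a_pb * effect_sizes[["NOTCH4"]]
      }
      if (cond %in% c("HHa", "HH") && genos[[i]][["CAT"]] %in% c("CT", "TT")) {
        m_pb <- m_pb / effect_sizes[["CAT"]]
        a_pb <- a_pb / effect_sizes[["CAT"]]
      }
      if (m_pb > 1 || m_pb < 0) {
        if (!clip_warned) {
          warning("PB depth clipped to [0, 1] for some records")
          clip_warned <- TRUE
        }
        m_pb <- min(max(m_pb, 0), 1)
      }
      cfg <- synthetic_config(
        f_resp = pr$f_resp, f_mod = base_cfg$f_mod,
        f_heart = pr$f_heart + subj_fh[i],
        m_pb = m_pb, a_rsa = base_cfg$a_rsa, a_pb_hr = a_pb,
        b_base = pr$b_base * (m_pb / max(pr$m_pb, 1e-9)),
        apnoea_duty = if (m_pb > 0.3) base_cfg$apnoea_duty else 0,
        phi_lag = base_cfg$phi_lag, noise_sd = base_cfg$noise_sd,
        duration_s = base_cfg$duration_s, fs = base_cfg$fs,
        freq_jitter_sd = base_cfg$freq_jitter_sd,
        seed = (seed + 7919L * i + 104729L * match(cond, names(profiles))) %%
          .Machine$integer.max)
      sigs <- list()
      if ("resp" %in% channels) sigs$resp <- generate_respiration(cfg)
      if (any(c("ihr", "ecg") %in% channels)) {
        h <- generate_heart(cfg, with_ecg = "ecg" %in% channels)
        if ("ihr" %in% channels) sigs$ihr <- h$ihr
        if ("ecg" %in% channels) sigs$ecg <- h$ecg
      }
      if ("ldf_left" %in% channels)
        sigs$ldf_left <- generate_ldf(cfg, label = "ldf_left")
      if ("ldf_right" %in% channels)
        sigs$ldf_right <- generate_ldf(cfg, pb_lag = 0.05, label = "ldf_right")
      records[[length(records) + 1L]] <-
        subject_record(sprintf("S%02d", i), cond, sigs, genos[[i]])
    }
  }
  records
}

#' Write a genotype table for a cohort
#'
#' TSV with columns `subject`, `gene`, `code`, one row per subject-gene pair.
#'
#' @param cohort List of [subject_record()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(cohort, path) {
  subj <- unique(vapply(cohort, function(r) r$subject_id, character(1)))
  rows <- do.call(rbind, lapply(cohort[match(subj, vapply(cohort, function(r)
    r$subject_id, character(1)))], function(r)
      data.frame(subject = r$subject_id, gene = names(r$genotypes),
                 code = unname(r$genotypes))))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype table
#' @param path TSV with columns `subject`, `gene`, `code`.
#' @return Named list, subject -> named character vector of codes.
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, colClasses = "character")
  stopifnot(all(c("subject", "gene", "code") %in% names(df)))
  out <- split(df, df$subject)
  lapply(out, function(d) setNames(d$code, d$gene))
}
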