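#' Analysis run configuration
#'
#' Bundles every tunable of the end-to-end analysis. Defaults mirror the
#' study protocol: IHR ridge band 0.5-2 Hz, respiration ridge band
#' 0.145-0.6 Hz, transform range 0.005-2 Hz, modulation band 0.03-0.15 Hz,
#' lognormal wavelet with central frequency 1, working rate 40 Hz, 100 IAAFT
#' surrogates, 95th-percentile threshold, alpha 0.05.
#'
#' @param ... Overrides of the default fields (see Details).
#' @details Fields: `band_ihr`, `band_resp`, `band_transform`, `band_mod`
#'   (each `c(lo, hi)` Hz); `wavelet`, `f0`, `nv`; `n_surrogates`,
#'   `percentile`; `alpha`; `fs_work`; `seed`; `genes` (genes to test);
#'   `synthetic` (argument list for [generate_cohort()], used when no input
#'   directory is given).
#' @return A validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    band_ihr = c(0.5, 2), band_resp = c(0.145, 0.6),
    band_transform = c(0.005, 2), band_mod = c(0.03, 0.15),
    wavelet = "lognormal", f0 = 1, nv = 32,
    n_surrogates = 100L, percentile = 95, alpha = 0.05,
    fs_work = 40, seed = 1L, genes = c("NOTCH4", "CAT"),
    synthetic = list())
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  cfg <- utils::modifyList(cfg, over)
  for (b in c("band_ihr", "band_resp", "band_mod"))
    if (cfg[[b]][1] < cfg$band_transform[1] ||
        cfg[[b]][2] > cfg$band_transform[2])
      stop(b, " must be nested within band_transform")
  if (cfg$n_surrogates < 1L) stop("n_surrogates must be >= 1")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys mirror [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) run_config(yaml::read_yaml(path))

#' Write a synthetic cohort to a directory
#'
#' One TSV per subject-condition record (the documented dialect) plus a
#' `genotypes.tsv` table, so a simulated cohort can be re-analysed from disk
#' exactly like recorded data.
#'
#' @param cohort List of [subject_record()]s, e.g. from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in cohort)
    write_signals(r$signals,
                  file.path(dir, sprintf("%s_%s.tsv", r$subject_id,
                                         r$condition)))
  write_genotypes(cohort, file.path(dir, "genotypes.tsv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Directory containing `<subject>_<condition>.tsv` files and
#'   `genotypes.tsv`.
#' @return List of [subject_record()]s.
#' @export
read_cohort <- function(dir) {
  genos <- read_genotypes(file.path(dir, "genotypes.tsv"))
  files <- list.files(dir, pattern = "^S.*_(NN|NHa|NH|HHa|HH)\\.tsv$",
                      full.names = TRUE)
  if (!length(files)) stop("no record files found in ", dir)
  lapply(files, function(f) {
    nm <- sub("\\.tsv$", "", basename(f))
    parts <- strsplit(nm, "_")[[1L]]
    subject_record(parts[1L], parts[2L], read_signals(f),
                   genos[[parts[1L]]])
  })
}

# Analyse one record: rates, spectra, cardiorespiratory coherence.
analyse_record <- function(rec, cfg) {
  sigs <- rec$signals
  # working-rate copies
  for (nm in names(sigs))
    if (sigs[[nm]]$fs > cfg$fs_work)
      sigs[[nm]] <- resample_signal(sigs[[nm]], cfg$fs_work)
  if (is.null(sigs$resp)) stop("record ", rec$subject_id, "/", rec$condition,
                               " has no respiration channel")
  # IHR: from the ECG transform ridge when no precomputed series is present
  if (is.null(sigs$ihr)) {
    if (is.null(sigs$ecg)) stop("record needs an 'ihr' or 'ecg' channel")
    sigs$ihr <- ihr_from_ecg(sigs$ecg, band = cfg$band_ihr,
                             fs_out = cfg$fs_work, nv = cfg$nv,
                             wavelet = cfg$wavelet, f0 = cfg$f0)$ihr
  }
  # instantaneous respiration rate from the respiration transform ridge
  tfr_resp_band <- cwt_tfr(sigs$resp, fmin = cfg$band_resp[1],
                           fmax = cfg$band_resp[2], nv = cfg$nv,
                           wavelet = cfg$wavelet, f0 = cfg$f0)
  resp_rate <- rate_series(extract_ridge(tfr_resp_band, cfg$band_resp),
                           fs_out = cfg$fs_work, label = "resp_rate")
  # full-range transforms of IHR and respiration for power + coherence;
  # the two transforms must share one time grid, so crop both channels to
  # their overlapping span on the common working-rate grid
  t_start <- max(sigs$resp$t0, sigs$ihr$t0)
  i_resp <- as.integer(round((t_start - sigs$resp$t0) * cfg$fs_work))
  i_ihr <- as.integer(round((t_start - sigs$ihr$t0) * cfg$fs_work))
  n <- min(length(sigs$resp$samples) - i_resp,
           length(sigs$ihr$samples) - i_ihr)
  resp_cut <- uniform_signal(sigs$resp$samples[i_resp + seq_len(n)],
                             sigs$resp$fs, "resp", t0 = t_start)
  ihr_cut <- uniform_signal(sigs$ihr$samples[i_ihr + seq_len(n)],
                            sigs$ihr$fs, "ihr", t0 = t_start)
  tfr_ihr <- cwt_tfr(ihr_cut, fmin = cfg$band_transform[1],
                     fmax = cfg$band_transform[2], nv = cfg$nv,
                     wavelet = cfg$wavelet, f0 = cfg$f0)
  tfr_resp <- cwt_tfr(resp_cut, fmin = cfg$band_transform[1],
                      fmax = cfg$band_transform[2], nv = cfg$nv,
                      wavelet = cfg$wavelet, f0 = cfg$f0)
  coh <- phase_coherence(tfr_ihr, tfr_resp)   # positive = respiration leads
  thr <- coherence_threshold(ihr_cut, resp_cut, n = cfg$n_surrogates,
                             percentile = cfg$percentile, seed = cfg$seed,
                             fmin = cfg$band_transform[1],
                             fmax = cfg$band_transform[2], nv = cfg$nv,
                             wavelet = cfg$wavelet, f0 = cfg$f0)
  coh <- apply_threshold(coh, thr)
  list(subject_id = rec$subject_id, condition = rec$condition,
       ihr_summary = rate_summary(sigs$ihr),
       resp_summary = rate_summary(resp_rate),
       spec_resp = normalise_spectrum(time_average_power(tfr_resp)),
       spec_ihr = normalise_spectrum(time_average_power(tfr_ihr)),
       coh = coh)
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest (or synthesis), preprocessing, wavelet transforms,
#' ridge extraction, cardiorespiratory phase coherence with IAAFT-surrogate
#' thresholds, modulation-band statistics, and the nonparametric group
#' comparisons, writing TSV tables and a JSON manifest to `outdir`. Every
#' number in the tables is produced by a module function; the orchestrator
#' only sequences them. A run is exactly reproducible from its manifest.
#'
#' @param config A [run_config()] (or list of overrides).
#' @param outdir Output directory; created if needed. `NULL` skips writing.
#' @param cohort Optional list of [subject_record()]s; when `NULL`, a
#'   synthetic cohort is generated from `config$synthetic` and
#'   `config$seed`, or read from `config$input_dir` if that is set.
#' @return A `pipeline_result` list: `rates` (per-record summaries),
#'   `band_stats`, `group_spectra`, `condition_tests`, `genotype_tests`,
#'   `records` (per-record analyses), `config`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL, cohort = NULL) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  if (is.null(cohort)) {
    cohort <- if (!is.null(config$input_dir)) read_cohort(config$input_dir)
    else do.call(generate_cohort,
                 utils::modifyList(list(seed = config$seed),
                                   config$synthetic))
  }
  results <- lapply(cohort, function(rec) analyse_record(rec, config))
  rates <- do.call(rbind, lapply(results, function(r)
    data.frame(subject = r$subject_id, condition = r$condition,
               ihr_mean = r$ihr_summary$mean, ihr_sd = r$ihr_summary$sd,
               ihr_cv = r$ihr_summary$cv, resp_mean = r$resp_summary$mean,
               resp_sd = r$resp_summary$sd, resp_cv = r$resp_summary$cv)))
  band_stats <- collect_band_stats(results, config$band_mod[1],
                                   config$band_mod[2], use = "adjusted")
  conds <- split(results, vapply(results, `[[`, character(1), "condition"))
  group_spectra <- lapply(conds, function(rs) list(
    resp = group_mean_spectra(lapply(rs, `[[`, "spec_resp")),
    ihr = group_mean_spectra(lapply(rs, `[[`, "spec_ihr"))))
  condition_tests <- list()
  for (col in c("ihr_mean", "ihr_sd", "ihr_cv", "resp_mean", "resp_sd",
                "resp_cv"))
    if (length(unique(rates$condition)) >= 2L)
      condition_tests[[col]] <- condition_comparison(
        data.frame(condition = rates$condition, value = rates[[col]]),
        alpha = config$alpha)
  if (length(unique(band_stats$condition)) >= 2L)
    condition_tests[["band_coherence"]] <- condition_comparison(
      band_stats, alpha = config$alpha)
  genos <- cohort_genotypes(cohort)
  genotype_tests <- list()
  for (cond in unique(band_stats$condition))
    for (gene in config$genes) {
      nm <- paste(cond, gene, sep = ".")
      genotype_tests[[nm]] <- tryCatch(
        genotype_comparison(band_stats[band_stats$condition == cond, ],
                            genos, gene, alpha = config$alpha,
                            merge_hom = !identical(gene, "NOTCH4")),
        error = function(e) NULL)
    }
  genotype_tests <- Filter(Negate(is.null), genotype_tests)
  out <- structure(list(rates = rates, band_stats = band_stats,
                        group_spectra = group_spectra,
                        condition_tests = condition_tests,
                        genotype_tests = genotype_tests,
                        records = results, config = config),
                   class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_result(out, outdir)
  out
}

write_pipeline_result <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.table(res$rates, file.path(outdir, "rates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$band_stats, file.path(outdir, "band_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (cond in names(res$group_spectra)) {
    write_spectrum(res$group_spectra[[cond]]$resp,
                   file.path(outdir, sprintf("spectrum_resp_%s.tsv", cond)))
    write_spectrum(res$group_spectra[[cond]]$ihr,
                   file.path(outdir, sprintf("spectrum_ihr_%s.tsv", cond)))
  }
  for (r in res$records)
    write_coherence(r$coh, file.path(outdir, sprintf("coherence_%s_%s.tsv",
                                                     r$subject_id,
                                                     r$condition)))
  if (length(res$condition_tests))
    write_group_tests(res$condition_tests,
                      file.path(outdir, "condition_tests.tsv"))
  if (length(res$genotype_tests))
    write_group_tests(res$genotype_tests,
                      file.path(outdir, "genotype_tests.tsv"))
  cfg <- unclass(res$config)
  manifest <- list(
    package = "cardiocoh",
    version = as.character(utils::packageVersion("cardiocoh")),
    config = cfg,
    n_records = length(res$records),
    n_tests = sum(vapply(c(res$condition_tests, res$genotype_tests),
                         `[[`, integer(1), "n_tests")),
    phase_convention = "phase_diff = Phi(resp) - Phi(ihr); positive = respiration leads")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d records, %d conditions\n",
              length(x$records), length(x$group_spectra)))
  cat(sprintf("  statistical tests run (uncorrected): %d\n",
              sum(vapply(c(x$condition_tests, x$genotype_tests), `[[`,
                         integer(1), "n_tests"))))
  if (length(x$condition_tests)) {
    cat("  condition comparisons (Kruskal-Wallis p):\n")
    for (nm in names(x$condition_tests))
      cat(sprintf("    %-14s p = %.4g\n", nm, x$condition_tests[[nm]]$p))
  }
  if (length(x$genotype_tests)) {
    cat("  genotype comparisons (Kruskal-Wallis p):\n")
    for (nm in names(x$genotype_tests))
      cat(sprintf("    %-14s p = %.4g\n", nm, x$genotype_tests[[nm]]$p))
  }
  invisible(x)
}
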