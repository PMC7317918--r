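#' Kruskal-Wallis test across groups
#'
#' Rank-based omnibus test that two or more groups share the same median;
#' the statistic uses the standard tie correction and the p-value comes from
#' the chi-square approximation with `k - 1` degrees of freedom (via
#' [stats::kruskal.test()]). The degenerate case of all values identical is
#' returned as `H = 0`, `p = 1`.
#'
#' @param groups Named list of numeric vectors, one per group (each
#'   nonempty; at least two groups).
#' @return List with `H`, `p`, `df`, `n` (total observations).
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(!vapply(groups, length, integer(1)))) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  if (diff(range(x)) == 0)
    return(list(H = 0, p = 1, df = length(groups) - 1L, n = length(x)))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), n = length(x))
}

#' Wilcoxon rank-sum test for two groups
#'
#' Two-sided test of equal medians. Exact enumeration is used when the
#' combined sample size is at most 12 and there are no ties; otherwise the
#' normal approximation with continuity and tie correction is used (via
#' [stats::wilcox.test()]).
#'
#' @param x,y Numeric vectors, both nonempty.
#' @return List with `W` (rank-sum statistic of `x`, Mann-Whitney form) and
#'   `p` (two-sided).
#' @export
rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' Collect per-subject modulation-band coherence statistics
#'
#' One row per subject-condition pair; missing recordings are simply absent
#' rows (unbalanced designs are analysed complete-case per comparison).
#'
#' @param results List of per-record analysis results, each a list with
#'   `subject_id`, `condition`, and a `coherence_spectrum` under `coh`.
#' @param f_lo,f_hi Band edges in Hz (default the 0.03-0.15 Hz modulation
#'   band).
#' @param use Passed to [band_mean()].
#' @return `data.frame` with columns `subject`, `condition`, `value`.
#' @export
collect_band_stats <- function(results, f_lo = 0.03, f_hi = 0.15,
                               use = c("adjusted", "raw")) {
  use <- match.arg(use)
  do.call(rbind, lapply(results, function(r)
    data.frame(subject = r$subject_id, condition = r$condition,
               value = band_mean(r$coh, f_lo, f_hi, use = use))))
}

#' Compare a statistic across genotype groups in one condition
#'
#' Groups the per-subject values by genotype code for one gene (2 or 3
#' groups; normal / heterozygous / homozygous) and runs the Kruskal-Wallis
#' test; pairwise rank-sum tests are run only when the omnibus test is
#' significant at `alpha`. Empty genotype groups are dropped with a warning.
#'
#' @param stats `data.frame` with columns `subject` and `value` (one
#'   condition's rows).
#' @param genotypes Named list subject -> named character vector of codes
#'   (as from [read_genotypes()]), or a `subject_record` cohort.
#' @param gene Gene name, e.g. `"NOTCH4"` or `"CAT"`.
#' @param alpha Significance level gating the pairwise tests (default 0.05).
#' @param merge_hom Merge the homozygous-variant code into the heterozygous
#'   group (normal vs carrier split). A separate homozygous group is kept
#'   only where enough homozygotes exist, typically for NOTCH4; default
#'   `FALSE`.
#' @return A `group_test` object: `grouping`, `groups` (values per label),
#'   `medians`, `H`, `p`, `pairwise` (data.frame or NULL), `n_tests`.
#' @export
genotype_comparison <- function(stats, genotypes, gene, alpha = 0.05,
                                merge_hom = FALSE) {
  if (length(genotypes) && inherits(genotypes[[1L]], "subject_record"))
    genotypes <- cohort_genotypes(genotypes)
  miss <- setdiff(stats$subject, names(genotypes))
  if (length(miss)) stop("no genotype for subject(s): ",
                         paste(miss, collapse = ", "))
  code <- vapply(genotypes[stats$subject], function(g) g[[gene]], character(1))
  if (merge_hom) {
    # homozygous-variant codes join the heterozygous (carrier) group
    code[code == "AA"] <- "GA"
    code[code == "TT"] <- "CT"
  }
  groups <- split(stats$value, code)
  empty <- !lengths(groups)
  if (any(empty)) {
    warning("dropping empty genotype group(s): ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  if (length(groups) < 2L)
    stop("fewer than 2 genotype groups present for ", gene)
  make_group_test(groups, grouping = paste0("genotype(", gene, ")"),
                  alpha = alpha)
}

#' Compare a statistic across exposure conditions
#'
#' Kruskal-Wallis across the condition groups; pairwise rank-sum tests where
#' the omnibus test is significant at `alpha`. No multiple-testing
#' correction is applied; `n_tests` counts the tests performed so reports
#' can state it.
#'
#' @param stats `data.frame` with columns `condition` and `value`.
#' @param alpha Significance level (default 0.05).
#' @return A `group_test` object (see [genotype_comparison()]).
#' @export
condition_comparison <- function(stats, alpha = 0.05) {
  groups <- split(stats$value, stats$condition)
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) stop("need at least 2 conditions")
  make_group_test(groups, grouping = "condition", alpha = alpha)
}

make_group_test <- function(groups, grouping, alpha) {
  kw <- kruskal_wallis(groups)
  pairwise <- NULL
  n_tests <- 1L
  if (is.finite(kw$p) && kw$p < alpha) {
    labs <- names(groups)
    cmb <- utils::combn(length(labs), 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      a <- cmb[1, j]; b <- cmb[2, j]
      rs <- rank_sum(groups[[a]], groups[[b]])
      data.frame(group1 = labs[a], group2 = labs[b], W = rs$W, p = rs$p)
    }))
    n_tests <- n_tests + ncol(cmb)
  }
  structure(list(grouping = grouping, groups = groups,
                 medians = vapply(groups, median, numeric(1)),
                 H = kw$H, p = kw$p, pairwise = pairwise, n_tests = n_tests,
                 alpha = alpha),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s: H = %.4g, p = %.4g (%d groups, n = %d; %d test%s, no multiplicity correction)\n",
              x$grouping, x$H, x$p, length(x$groups),
              sum(lengths(x$groups)), x$n_tests,
              if (x$n_tests == 1L) "" else "s"))
  for (g in names(x$groups))
    cat(sprintf("  %-4s n = %2d  median = %.4g\n", g,
                length(x$groups[[g]]), x$medians[[g]]))
  if (!is.null(x$pairwise)) {
    cat("  pairwise rank-sum:\n")
    for (j in seq_len(nrow(x$pairwise)))
      cat(sprintf("    %s vs %s: W = %g, p = %.4g\n", x$pairwise$group1[j],
                  x$pairwise$group2[j], x$pairwise$W[j], x$pairwise$p[j]))
  }
  invisible(x)
}

# genotype map of a cohort: subject -> codes
cohort_genotypes <- function(cohort) {
  subj <- vapply(cohort, function(r) r$subject_id, character(1))
  out <- lapply(cohort[!duplicated(subj)], function(r) r$genotypes)
  names(out) <- subj[!duplicated(subj)]
  out
}

#' Write a group test (and its pairwise follow-ups) as TSV
#' @param tests Named list of `group_test` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_tests <- function(tests, path) {
  rows <- do.call(rbind, lapply(names(tests), function(nm) {
    x <- tests[[nm]]
    data.frame(test = nm, grouping = x$grouping,
               groups = paste(names(x$groups), collapse = ","),
               n = paste(lengths(x$groups), collapse = ","),
               H = x$H, p = x$p, n_tests = x$n_tests)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
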