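test_that("Kruskal-Wallis H matches a first-principles oracle and permutation moments", {
  g <- list(a = c(1, 5, 8), b = c(2, 6, 7), c = c(3, 4, 9))
  kw <- kruskal_wallis(g)
  expect_equal(kw$H, kw_h_direct(g), tolerance = 1e-12)
  expect_equal(kw$df, 2L)
  # permutation distribution of H over all-distinct samples: mean is k - 1
  g2 <- list(x = c(0.3, 1.2, 2.7), y = c(0.9, 3.1, 4.4))
  hs <- enumerate_h(g2)
  expect_equal(mean(hs), 1, tolerance = 1e-10)
  g3 <- list(x = c(1, 4), y = c(2, 7, 8), z = c(3, 6, 9))
  hs3 <- enumerate_h(g3)
  expect_equal(mean(hs3), 2, tolerance = 1e-10)
  expect_equal(kruskal_wallis(g3)$H, kw_h_direct(g3), tolerance = 1e-12)
})

test_that("degenerate and well-separated groups behave as contracted", {
  expect_equal(kruskal_wallis(list(a = c(1, 1), b = c(1, 1)))[c("H", "p")],
               list(H = 0, p = 1))
  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(10, 11, 12)))
  expect_lt(kw$p, 0.1)
  expect_error(kruskal_wallis(list(a = numeric(0), b = 1)), "empty")
  # rank-based: invariant under monotone transformation
  g <- list(a = c(0.1, 0.7, 1.3), b = c(0.4, 2.2, 3.3), c = c(0.2, 0.9, 5))
  expect_equal(kruskal_wallis(g)$H,
               kruskal_wallis(lapply(g, exp))$H, tolerance = 1e-12)
})

test_that("rank-sum p-values match exhaustive enumeration for small samples", {
  # [1,2] vs [3,4]: of C(4,2) = 6 assignments, the observed split is one of
  # the two most extreme, so the exact two-sided p is 2/6 = 1/3
  rs <- rank_sum(c(1, 2), c(3, 4))
  expect_equal(rs$p, 1 / 3, tolerance = 1e-12)
  # enumeration oracle for a 3 + 3 all-distinct sample
  x <- c(1.1, 2.3, 9.9); y <- c(4.2, 5.0, 7.7)
  w_obs <- sum(rank(c(x, y))[1:3]) - 6        # Mann-Whitney U of x
  picks <- utils::combn(6, 3)
  vals <- c(x, y)
  us <- apply(picks, 2, function(id)
    sum(rank(vals)[id]) - 6)
  p_enum <- mean(abs(us - 4.5) >= abs(w_obs - 4.5))
  expect_equal(rank_sum(x, y)$p, p_enum, tolerance = 1e-10)
  # identical groups, and antisymmetry under swapping
  expect_equal(rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  a <- c(0.5, 1.7, 2.2); b <- c(0.9, 3.3, 4.1)
  expect_equal(rank_sum(a, b)$p, rank_sum(b, a)$p, tolerance = 1e-12)
})

test_that("null Kruskal-Wallis rejection rate is close to the nominal level", {
  set.seed(14)
  rej <- mean(replicate(1000, {
    g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8))
    kruskal_wallis(g)$p < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("genotype comparison groups by code, gates pairwise tests, merges carriers", {
  stats <- data.frame(subject = sprintf("S%02d", 1:12),
                      value = c(1:4, 11:14, 21:24) / 10)
  genos <- setNames(lapply(c(rep("GG", 4), rep("GA", 4), rep("AA", 4)),
                           function(code) c(NOTCH4 = code)),
                    stats$subject)
  gt <- genotype_comparison(stats, genos, "NOTCH4")
  expect_length(gt$groups, 3)
  expect_lt(gt$p, 0.05)
  expect_false(is.null(gt$pairwise))           # follow-up only when significant
  expect_equal(gt$n_tests, 1L + 3L)
  gm <- genotype_comparison(stats, genos, "NOTCH4", merge_hom = TRUE)
  expect_length(gm$groups, 2)
  expect_equal(lengths(gm$groups)[["GA"]], 8L)
  # single genotype present -> error
  mono <- setNames(lapply(1:12, function(i) c(NOTCH4 = "GG")), stats$subject)
  expect_error(genotype_comparison(stats, mono, "NOTCH4"), "fewer than 2")
  expect_error(genotype_comparison(stats, genos[1:3], "NOTCH4"), "no genotype")
})

test_that("condition comparison runs pairwise follow-ups only when the omnibus is significant", {
  set.seed(3)
  stats <- data.frame(condition = rep(c("NN", "NH", "HH"), each = 6),
                      value = c(rnorm(6), rnorm(6) + 3, rnorm(6) + 3.2))
  ct <- condition_comparison(stats)
  expect_lt(ct$p, 0.05)
  expect_equal(nrow(ct$pairwise), 3L)
  null_stats <- data.frame(condition = rep(c("NN", "NH"), each = 6),
                           value = rep(seq(0.1, 0.6, 0.1), 2))
  nt <- condition_comparison(null_stats)
  expect_gt(nt$p, 0.5)
  expect_null(nt$pairwise)
  expect_error(condition_comparison(data.frame(condition = "NN", value = 1)),
               "at least 2")
})

test_that("band statistics tables carry one row per subject-condition pair", {
  freqs <- 0.02 * 2^((0:99) / 32)
  mk <- function(v) structure(
    list(freqs = freqs, raw_coh = rep(v, 100), adj_coh = rep(v, 100),
         threshold = rep(0, 100), phase_diff = rep(0, 100),
         n_valid = rep(5L, 100)), class = "coherence_spectrum")
  res <- list(
    list(subject_id = "S01", condition = "NN", coh = mk(0.1)),
    list(subject_id = "S01", condition = "NH", coh = mk(0.4)),
    list(subject_id = "S02", condition = "NN", coh = mk(0.2)))
  tab <- collect_band_stats(res, use = "adjusted")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$value, c(0.1, 0.4, 0.2))
})
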