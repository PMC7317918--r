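# first-principles Kruskal-Wallis H (tie-corrected) and its exhaustive
# permutation distribution for small samples; oracles independent of the
# package implementation

kw_h_direct <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  r <- rank(x)
  n <- length(x)
  rg <- split(r, rep(seq_along(groups), lengths(groups)))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(rg, function(z) length(z) * (mean(z) - (n + 1) / 2)^2,
               numeric(1)))
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

enumerate_h <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  n <- length(x)
  picks <- utils::combn(n, sizes[1])
  hs <- numeric(0)
  for (j in seq_len(ncol(picks))) {
    g1 <- picks[, j]
    rest <- setdiff(seq_len(n), g1)
    if (length(sizes) == 2L) {
      hs <- c(hs, kw_h_direct(list(x[g1], x[rest])))
    } else {
      picks2 <- utils::combn(length(rest), sizes[2])
      for (l in seq_len(ncol(picks2))) {
        g2 <- rest[picks2[, l]]
        g3 <- setdiff(rest, g2)
        hs <- c(hs, kw_h_direct(list(x[g1], x[g2], x[g3])))
      }
    }
  }
  hs
}
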