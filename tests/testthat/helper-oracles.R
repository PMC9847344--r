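# Independent oracles and fixture builders used across the suite.

# Exhaustive enumeration of all monotone matchings between peak index sets
# 1..ne and 1..nt, maximizing the sum of S[i, j] plus gap_score per unmatched
# peak. Recursion over (i, j): skip exp i, skip theo j, or match (i, j).
# Exponential; for oracle use at ne, nt <= 7 only.
brute_force_align <- function(S, gap = 0) {
  ne <- nrow(S)
  nt <- ncol(S)
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (i > ne) return(gap * (nt - j + 1))
    if (j > nt) return(gap * (ne - i + 1))
    key <- paste0(i, ",", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- max(rec(i + 1, j) + gap,
                rec(i, j + 1) + gap,
                if (is.finite(S[i, j])) rec(i + 1, j + 1) + S[i, j] else -Inf)
    memo[[key]] <- best
    best
  }
  rec(1, 1)
}

# Score matrix exactly as align_peaks builds it (normalized lists, mu applied
# to theoretical positions), evaluated via the exported scalar operations.
score_matrix <- function(exp_peaks, theo_peaks, cfg) {
  e <- normalize_intensities(exp_peaks)
  t <- normalize_intensities(theo_peaks)
  S <- matrix(0, nrow(e), nrow(t))
  for (i in seq_len(nrow(e))) {
    for (j in seq_len(nrow(t))) {
      S[i, j] <- pair_score(e[i, ], t[j, ], cfg)
    }
  }
  S
}

# Random valid peak list for property-style tests.
random_peak_list <- function(n, modality = "IR", origin = "experimental",
                             lo = 1000, hi = 1500) {
  x0 <- sort(stats::runif(n, lo, hi))
  while (n > 1 && min(diff(x0)) < 1) x0 <- sort(stats::runif(n, lo, hi))
  peak_list(x0, stats::runif(n, 0.1, 1), stats::runif(n, 6, 18),
            stats::runif(n, 0, 1), modality, origin)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * pmax(abs(expected), 1e-12)),
              label = paste0("relative error within ", tol))
}
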