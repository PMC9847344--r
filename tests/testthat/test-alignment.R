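test_that("intensity normalization scales to unit maximum and keeps signs", {
  pl <- peak_list(c(1100, 1200), c(2, 4), c(10, 10))
  expect_equal(normalize_intensities(pl)$I, c(0.5, 1))
  expect_equal(normalize_intensities(normalize_intensities(pl))$I, c(0.5, 1))

  vcd <- peak_list(c(1100, 1200), c(-3, 1.5), c(10, 10), modality = "VCD")
  expect_equal(normalize_intensities(vcd)$I, c(-1, 0.5))

  zero <- peak_list(c(1100, 1200), c(1, 1), c(10, 10))
  zero$I <- c(0, 0)
  expect_error(normalize_intensities(zero), "all-zero")
})

test_that("the mollifier is a smooth bump with compact support", {
  expect_equal(mollifier(0, 30), 1)
  expect_equal(mollifier(30, 30), 0)
  expect_equal(mollifier(-30, 30), 0)
  expect_equal(mollifier(45, 30), 0)
  # frozen closed form at half cutoff: exp(1 - 1/(1 - 1/4)) = exp(-1/3)
  expect_equal(mollifier(15, 30), exp(-1 / 3), tolerance = 1e-14)
  # even, strictly decreasing in |delta| on the support
  d <- seq(0, 29.9, 0.1)
  v <- mollifier(d, 30)
  expect_equal(mollifier(-d, 30), v)
  expect_true(all(diff(v) < 0))
  expect_error(mollifier(1, 0), "cutoff")
})

test_that("pair scores multiply the three mollifier components", {
  cfg <- scoring_config(mu = 1, C_nu = 30, C_I = 0.5, C_w = 20)
  a <- peak_list(1200, 1, 12, 0.5)
  expect_equal(pair_score(a, a, cfg), 1)

  # any component at its cutoff annihilates the score
  far <- peak_list(1230, 1, 12, 0.5)
  expect_equal(pair_score(a, far, cfg), 0)
  wide <- peak_list(1200, 1, 32, 0.5)
  expect_equal(pair_score(a, wide, cfg), 0)
  dim_ <- peak_list(1200, 1, 12, 0.5)
  dim_$I <- 0.4  # delta 0.6 > C_I: high- vs low-intensity peaks never match
  expect_equal(pair_score(a, dim_, cfg), 0)

  # all three deltas at half cutoff multiply independently
  b <- peak_list(1215, 1, 22, 0.5)
  b$I <- 0.75
  expect_equal(pair_score(a, b, cfg),
               mollifier(15, 30) * mollifier(0.25, 0.5) * mollifier(10, 20))

  # mu scales the theoretical position before the frequency component
  theo <- peak_list(1200 / 0.975, 1, 12, 0.5, origin = "theoretical")
  expect_equal(pair_score(a, theo, scoring_config(mu = 0.975)), 1)

  # VCD signs are ignored in scoring: magnitudes are compared
  vp <- peak_list(1200, 1, 12, 0.5, modality = "VCD")
  vn <- vp
  vn$I <- -1
  expect_equal(pair_score(vp, vn, cfg), 1)

  # symmetric once scaling is applied
  expect_equal(pair_score(a, b, cfg), pair_score(b, a, cfg))
})

test_that("the legacy two-term score peaks at identity and decays with distance", {
  cfg <- legacy_scoring_config(sigma1 = 0.3, sigma2 = 20, mu = 1)
  a <- peak_list(1200, 1, 12)
  expect_equal(legacy_pair_score(a, a, cfg), 1)
  # direct evaluation of the closed form for an arbitrary pair
  b <- peak_list(1212, 1, 12)
  b$I <- 0.8
  expect_equal(legacy_pair_score(a, b, cfg),
               exp(-0.2^2 / 0.3^2) * exp(-12^2 / 20^2))
  # only vanishes at infinite separation: still positive at five sigma
  far <- peak_list(1300, 1, 12)
  expect_gt(legacy_pair_score(a, far, cfg), 0)
  expect_lt(legacy_pair_score(a, far, cfg), 1e-8)
})

test_that("dynamic programming equals exhaustive enumeration of matchings", {
  cfg <- scoring_config()
  set.seed(7)
  for (rep in 1:60) {
    ne <- sample(1:7, 1)
    nt <- sample(1:7, 1)
    e <- random_peak_list(ne)
    t <- random_peak_list(nt, origin = "theoretical")
    al <- align_peaks(e, t, cfg)
    S <- score_matrix(e, t, cfg)
    expect_equal(al$raw_score, brute_force_align(S), tolerance = 1e-10)
    # order preservation and disjoint cover
    expect_true(all(diff(al$pairs$exp_idx) > 0))
    expect_true(all(diff(al$pairs$theo_idx) > 0))
    expect_setequal(c(al$pairs$exp_idx, al$exp_gaps), seq_len(ne))
    expect_setequal(c(al$pairs$theo_idx, al$theo_gaps), seq_len(nt))
    expect_true(all(al$pairs$score > 0))
    expect_true(al$score >= 0 && al$score <= 1)
  }
})

test_that("self-alignment is perfect and disjoint peaks yield zero", {
  e <- random_peak_list(5)
  t <- e
  t$origin <- "theoretical"
  al <- align_peaks(e, t)
  expect_equal(al$score, 1)
  expect_equal(nrow(al$pairs), 5)

  t2 <- peak_list(1400, 1, 12, origin = "theoretical")
  e2 <- peak_list(1100, 1, 12)
  al2 <- align_peaks(e2, t2)
  expect_equal(nrow(al2$pairs), 0)
  expect_equal(al2$score, 0)
  expect_equal(al2$exp_gaps, 1L)
  expect_equal(al2$theo_gaps, 1L)

  expect_error(align_peaks(e[0, ], t), "empty")
})

test_that("widening any cutoff never lowers the optimal score", {
  set.seed(11)
  for (rep in 1:10) {
    e <- random_peak_list(5)
    t <- random_peak_list(6, origin = "theoretical")
    base <- align_peaks(e, t, scoring_config(C_nu = 25, C_I = 0.4, C_w = 15))
    expect_gte(align_peaks(e, t, scoring_config(C_nu = 40, C_I = 0.4,
                                                C_w = 15))$score,
               base$score - 1e-12)
    expect_gte(align_peaks(e, t, scoring_config(C_nu = 25, C_I = 0.7,
                                                C_w = 15))$score,
               base$score - 1e-12)
    expect_gte(align_peaks(e, t, scoring_config(C_nu = 25, C_I = 0.4,
                                                C_w = 30))$score,
               base$score - 1e-12)
  }
})

test_that("shifting snaps matches and moves gaps with their nearest neighbor", {
  # identity: all peaks matched at their own positions
  e <- random_peak_list(4)
  t <- e
  t$origin <- "theoretical"
  al <- align_peaks(e, t)
  expect_equal(shift_theoretical(t, al, e)$x0, t$x0)

  # two matches shifted by +5 and -3; the unmatched peak closest to the first
  # follows its +5 shift
  e2 <- peak_list(c(1105, 1297), c(1, 1), c(12, 12))
  t2 <- peak_list(c(1100, 1150, 1300), c(1, 0.2, 1), c(12, 12, 12),
                  origin = "theoretical")
  t2$I <- c(1, 1, 1)  # make all matchable on intensity
  al2 <- align_peaks(e2, t2, scoring_config(C_nu = 20))
  expect_equal(nrow(al2$pairs), 2)
  shifted <- shift_theoretical(t2, al2, e2)
  expect_equal(shifted$x0, c(1105, 1155, 1297))

  # random instances against a direct re-implementation of the rule
  set.seed(23)
  for (rep in 1:20) {
    e3 <- random_peak_list(6)
    t3 <- random_peak_list(6, origin = "theoretical")
    al3 <- align_peaks(e3, t3)
    if (nrow(al3$pairs) == 0) next
    shifted3 <- shift_theoretical(t3, al3, e3)
    expected <- t3$x0
    mt <- al3$pairs$theo_idx
    delta <- e3$x0[al3$pairs$exp_idx] - t3$x0[mt]
    expected[mt] <- e3$x0[al3$pairs$exp_idx]
    for (k in setdiff(seq_len(6), mt)) {
      d <- abs(t3$x0[k] - t3$x0[mt])
      nb <- which(d == min(d))
      if (length(nb) > 1) nb <- nb[which.min(t3$x0[mt][nb])]
      expected[k] <- t3$x0[k] + delta[nb]
    }
    expect_equal(shifted3$x0, sort(expected))
  }

  # no matches: identity shift, flagged
  eu <- peak_list(1100, 1, 12)
  tu <- peak_list(1450, 1, 12, origin = "theoretical")
  alu <- align_peaks(eu, tu)
  su <- shift_theoretical(tu, alu, eu)
  expect_equal(su$x0, tu$x0)
  expect_true(attr(su, "identity_shift"))
})

test_that("multi-source alignment never crosses sources and splits cleanly", {
  cfg <- scoring_config()
  # disjoint ranges: identical to independent per-source alignments
  set.seed(31)
  for (rep in 1:10) {
    e_ir <- random_peak_list(4, "IR", lo = 1000, hi = 1180)
    t_ir <- random_peak_list(5, "IR", origin = "theoretical",
                             lo = 1000, hi = 1180)
    e_rm <- random_peak_list(4, "RAMAN", lo = 1300, hi = 1500)
    t_rm <- random_peak_list(3, "RAMAN", origin = "theoretical",
                             lo = 1300, hi = 1500)
    ms <- align_multisource(list(IR = e_ir, RAMAN = e_rm),
                            list(IR = t_ir, RAMAN = t_rm), cfg)
    ir <- align_peaks(e_ir, t_ir, cfg)
    rm <- align_peaks(e_rm, t_rm, cfg)
    expect_equal(ms$per_source$IR$pairs$exp_idx, ir$pairs$exp_idx)
    expect_equal(ms$per_source$IR$pairs$score, ir$pairs$score)
    expect_equal(ms$per_source$RAMAN$pairs$theo_idx, rm$pairs$theo_idx)
    expect_equal(ms$raw_score, ir$raw_score + rm$raw_score, tolerance = 1e-10)
  }

  # coincident frequencies: IR matches IR and Raman matches Raman, never cross
  e <- list(IR = peak_list(1200, 1, 12, modality = "IR"),
            RAMAN = peak_list(1200, 1, 12, modality = "RAMAN"))
  t <- list(IR = peak_list(1200, 1, 12, modality = "IR",
                           origin = "theoretical"),
            RAMAN = peak_list(1200, 1, 12, modality = "RAMAN",
                              origin = "theoretical"))
  ms <- align_multisource(e, t, cfg)
  expect_equal(nrow(ms$per_source$IR$pairs), 1)
  expect_equal(nrow(ms$per_source$RAMAN$pairs), 1)
  expect_equal(ms$per_source$IR$pairs$score, 1)
  expect_equal(ms$score, 1)

  expect_error(align_multisource(e, t["IR"], cfg), "same modalities")
})
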