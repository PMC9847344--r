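test_that("cubic-spline resampling interpolates nodes and linear ramps", {
  win <- analysis_window(1100, 1200, 1)
  grid <- seq(1000, 1500, 1)

  sp <- continuous_spectrum(grid, sin(grid / 40))
  rs <- resample(sp, win)
  expect_equal(rs$intensity, sin(seq(1100, 1200, 1) / 40), tolerance = 1e-12)

  ramp <- continuous_spectrum(grid, 0.002 * grid - 1)
  expect_equal(resample(ramp, win)$intensity,
               0.002 * seq(1100, 1200, 1) - 1, tolerance = 1e-9)

  # a Lorentzian sampled at 0.5 cm^-1 resampled to 1 cm^-1 agrees with the
  # direct band evaluation
  fine <- seq(1000, 1500, 0.5)
  lor <- continuous_spectrum(fine, band_value(fine, 1150, 1, 12, 1))
  rs2 <- resample(lor, win)
  direct <- band_value(seq(1100, 1200, 1), 1150, 1, 12, 1)
  expect_true(max(abs(rs2$intensity - direct)) < 1e-3 * max(direct))

  expect_error(resample(continuous_spectrum(1100:1150, rep(1, 51)), win),
               "beyond")
  expect_error(analysis_window(1500, 1000), "lo must be")
})

test_that("correlations match hand computations and flag degenerate input", {
  g <- 1001:1005
  a <- continuous_spectrum(g, c(1, 3, 2, 5, 4))
  b <- continuous_spectrum(g, c(2, 1, 4, 3, 6))
  expect_equal(pearson(a, a), 1)
  neg <- continuous_spectrum(g, -a$intensity)
  expect_equal(pearson(a, neg), -1)
  expect_equal(spearman(a, neg), -1)

  # hand-computed covariance ratio for the 5-point vectors
  expect_equal(pearson(a, b),
               sum((a$intensity - 3) * (b$intensity - 3.2)) /
                 sqrt(sum((a$intensity - 3)^2) * sum((b$intensity - 3.2)^2)))

  # rank invariance under monotone transforms; hand-ranked tie case
  expect_equal(spearman(a, continuous_spectrum(g, exp(a$intensity))), 1)
  tie <- continuous_spectrum(g, c(1, 2, 2, 3, 4))
  r1 <- rank(tie$intensity)
  r2 <- rank(b$intensity)
  expect_equal(spearman(tie, b),
               stats::cor(r1, r2))

  expect_error(pearson(a, continuous_spectrum(g, rep(1, 5))), "constant")
  expect_error(pearson(a, continuous_spectrum(1002:1006, 1:5)),
               "identical grid")
})

test_that("combined scores multiply and annihilate as expected", {
  expect_equal(combined_score(1, c(1, 1, 1, 1)), 1)
  expect_equal(combined_score(0.5, c(0.9, 0.8, 0.9, 0.8)), 0.2592)
  expect_equal(combined_score(0.7, c(0.9, 0, 0.8, 0.5)), 0)
  # an odd number of anti-correlated coefficients flips the sign; an even
  # number cancels, which is why the enantiomer call uses the signs directly
  expect_lt(combined_score(0.5, c(0.9, 0.9, -0.8, 0.7)), 0)
  expect_gt(combined_score(0.5, c(0.9, 0.9, -0.8, -0.7)), 0)
})

test_that("mu screening recovers a constructed systematic scale", {
  expect_length(default_mu_grid(), 17)
  expect_equal(range(default_mu_grid()), c(0.94, 1.02))

  # identical experimental and theoretical spectra peak at mu = 1
  cfg <- synthetic_config(n_peaks = 5, systematic_scale = 1, jitter_sd = 0,
                          intensity_noise_sd = 0, baseline_noise_sd = 0,
                          seed = 3)
  truth <- make_truth(cfg)
  spec <- render_experimental(truth, cfg)
  ens <- conformer_ensemble("self", list(list(
    id = "c1", dG = 0,
    spectra = list(IR = derive_theoretical(truth, cfg)))))
  self <- screen_mu(list(IR = spec), ens,
                    shape = band_shape("pseudo_voigt", 12, 0.5))
  expect_equal(self$best_mu, 1.0)

  # frequencies divided by 0.975 are recovered at mu = 0.975
  cfg2 <- synthetic_config(n_peaks = 6, systematic_scale = 0.975,
                           jitter_sd = 0.5, seed = 5)
  study <- make_synthetic_study(cfg2, k_decoys = 0, modalities = "IR")
  a <- screen_mu(study$experimental, study$ensembles[[1]])
  expect_equal(a$best_mu, 0.975)
  expect_equal(nrow(a$table), 17)
  # the score table is a deterministic function of the inputs
  a2 <- screen_mu(study$experimental, study$ensembles[[1]])
  expect_identical(a$table, a2$table)
})

test_that("flipping the theoretical VCD sign flips only the correlations", {
  cfg <- synthetic_config(n_peaks = 6, modality = "VCD", jitter_sd = 1,
                          seed = 9)
  truth <- make_truth(cfg)
  spec <- render_experimental(truth, cfg)
  theo <- derive_theoretical(truth, cfg)
  mirror <- line_spectrum(theo$wavenumber, -theo$intensity, "VCD", "mir")
  mk <- function(ls) conformer_ensemble("v", list(list(
    id = "c", dG = 0, spectra = list(VCD = ls))))
  grid <- default_mu_grid()
  a <- screen_mu(list(VCD = spec), mk(theo), mu_grid = grid)
  b <- screen_mu(list(VCD = spec), mk(mirror), mu_grid = grid)
  expect_equal(b$table$s, a$table$s, tolerance = 1e-9)
  expect_equal(b$table$rP_VCD, -a$table$rP_VCD, tolerance = 1e-9)
  expect_equal(b$table$rS_VCD, -a$table$rS_VCD, tolerance = 1e-9)

  i <- which(a$table$mu == a$best_mu)
  expect_equal(enantiomer_sign(a$table$rP_VCD[i], a$table$rS_VCD[i]),
               "correct_enantiomer")
  expect_equal(enantiomer_sign(b$table$rP_VCD[i], b$table$rS_VCD[i]),
               "mirror_enantiomer")
})

test_that("isomer ranking orders by combined score with a stable tie rule", {
  mk <- function(id, s) {
    structure(list(isomer_id = id, best_mu = 0.975, best_s_comb = s,
                   table = data.frame(), best_pairs = NULL,
                   modalities = "IR"),
              class = "isomer_assessment")
  }
  rk <- rank_isomers(list(mk("i0", 0.35), mk("i1", 0.14), mk("i2", 0.17),
                          mk("i3", 0.09)))
  expect_equal(rk$ranking$isomer, c("i0", "i2", "i1", "i3"))
  expect_equal(rk$ratio, 0.35 / 0.17)

  expect_null(rank_isomers(list(mk("only", 0.3)))$ratio)

  tied <- rank_isomers(list(mk("b", 0.2), mk("a", 0.2)))
  expect_equal(tied$ranking$isomer, c("a", "b"))
  expect_equal(tied$ratio, 1)
})

test_that("enantiomer calls follow the sign rule with an ambiguity band", {
  expect_equal(enantiomer_sign(0.7, 0.6), "correct_enantiomer")
  expect_equal(enantiomer_sign(-0.7, -0.6), "mirror_enantiomer")
  expect_equal(enantiomer_sign(0.4, -0.1), "ambiguous")
  expect_equal(enantiomer_sign(0.03, 0.9), "ambiguous")
})
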