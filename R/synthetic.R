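## Evaluate expr under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  expr
}

#' Configuration of the synthetic spectrum generator
#'
#' The generator emulates the error structure the alignment method assumes:
#' a systematic frequency compression of the theoretical (harmonic) spectrum
#' by a constant factor, an additional stochastic per-mode frequency error,
#' multiplicative intensity noise, band-shape mismatch between experiment
#' (pseudo-Voigt, variable width and mixing) and theory (fixed Lorentzian),
#' and additive baseline noise on the measured spectrum.
#'
#' @param n_peaks Number of ground-truth bands (>= 1).
#' @param window [analysis_window()] the bands live in.
#' @param systematic_scale True reciprocal scaling factor: theoretical
#'   frequencies are `x0 / systematic_scale`, so a screening over mu should
#'   recover `mu = systematic_scale`. Default 0.975, a typical harmonic
#'   scaling factor for hybrid functionals in the fingerprint region.
#' @param jitter_sd Standard deviation of the stochastic per-peak frequency
#'   error, cm^-1.
#' @param intensity_noise_sd Relative standard deviation of the intensity
#'   noise.
#' @param exp_fwhm_range Range of experimental band FWHMs, cm^-1.
#' @param theo_fwhm Theoretical broadening FWHM, cm^-1.
#' @param eta_range Range of experimental Lorentzian mixing fractions.
#' @param baseline_noise_sd Additive baseline noise as a fraction of the
#'   maximum intensity.
#' @param min_separation Minimum distance between truth bands, cm^-1; default
#'   half the mean experimental FWHM, so moderately overlapping bands occur
#'   but remain identifiable.
#' @param overlap_pair If `TRUE`, one extra pair of bands is forced closer
#'   than one FWHM to exercise the strong-overlap regime.
#' @param modality Modality label of the generated spectra.
#' @param seed Integer fixing all randomness of the module.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_peaks = 8, window = analysis_window(),
                             systematic_scale = 0.975, jitter_sd = 3,
                             intensity_noise_sd = 0.05,
                             exp_fwhm_range = c(8, 16), theo_fwhm = 12,
                             eta_range = c(0.3, 0.7),
                             baseline_noise_sd = 0.005,
                             min_separation = NULL, overlap_pair = FALSE,
                             modality = "IR", seed = 42) {
  stopifnot(n_peaks >= 1, jitter_sd >= 0, intensity_noise_sd >= 0,
            baseline_noise_sd >= 0, systematic_scale > 0)
  if (is.null(min_separation)) min_separation <- mean(exp_fwhm_range) / 2
  structure(list(n_peaks = n_peaks, window = window,
                 systematic_scale = systematic_scale, jitter_sd = jitter_sd,
                 intensity_noise_sd = intensity_noise_sd,
                 exp_fwhm_range = exp_fwhm_range, theo_fwhm = theo_fwhm,
                 eta_range = eta_range, baseline_noise_sd = baseline_noise_sd,
                 min_separation = min_separation, overlap_pair = overlap_pair,
                 modality = as_modality(modality), seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Draw ground-truth experimental bands
#'
#' Band positions are uniform in the window subject to a minimum mutual
#' separation (whole draws are rejected until the separation holds), heights
#' uniform in (0.2, 1\], widths uniform in the experimental FWHM range, and
#' mixing fractions uniform in the eta range. For VCD, signs are assigned at
#' random. Fully deterministic under the config seed.
#'
#' @param cfg A [synthetic_config()].
#' @return A [peak_list()] of origin `"experimental"`; the identity
#'   correspondence truth-band i <-> theoretical line i is stored in
#'   `attr(, "correspondence")`.
#' @export
make_truth <- function(cfg) {
  lo <- cfg$window$lo
  hi <- cfg$window$hi
  n <- cfg$n_peaks
  if ((hi - lo) < (n - 1) * cfg$min_separation) {
    stop("window too small for ", n, " peaks at min separation ",
         cfg$min_separation, call. = FALSE)
  }
  with_seed(cfg$seed, {
    pos <- NULL
    for (attempt in seq_len(1000L)) {
      cand <- sort(stats::runif(n, lo, hi))
      if (n == 1L || min(diff(cand)) >= cfg$min_separation) {
        pos <- cand
        break
      }
    }
    if (is.null(pos)) {
      stop("could not place ", n, " peaks at min separation ",
           cfg$min_separation, " in 1000 attempts", call. = FALSE)
    }
    if (cfg$overlap_pair) {
      anchor <- pos[which.max(c(Inf, diff(pos)))]
      pos <- sort(c(pos, anchor + 0.6 * min(cfg$exp_fwhm_range)))
      n <- n + 1L
    }
    I <- stats::runif(n, 0.2, 1)
    if (is_vcd(cfg$modality)) I <- I * sample(c(-1, 1), n, replace = TRUE)
    w <- stats::runif(n, cfg$exp_fwhm_range[1], cfg$exp_fwhm_range[2])
    eta <- stats::runif(n, cfg$eta_range[1], cfg$eta_range[2])
    out <- peak_list(pos, I, w, eta, cfg$modality, origin = "experimental")
    attr(out, "correspondence") <- seq_len(n)
    out
  })
}

#' Derive a theoretical line spectrum from truth bands
#'
#' Applies the inverse of the alignment's error model: frequencies are the
#' truth positions divided by the systematic scale plus Gaussian per-peak
#' jitter; intensities pick up multiplicative Gaussian noise (clipped positive
#' except for VCD).
#'
#' @param truth A [make_truth()] peak list.
#' @param cfg The [synthetic_config()] used to generate it.
#' @param conformer_id Identifier for the resulting line spectrum.
#' @param seed_offset Offset added to the config seed so that the different
#'   stochastic stages draw independent streams.
#' @return A [line_spectrum()].
#' @export
derive_theoretical <- function(truth, cfg, conformer_id = "conf1",
                               seed_offset = 1L) {
  n <- nrow(truth)
  with_seed(cfg$seed + seed_offset, {
    freq <- truth$x0 / cfg$systematic_scale +
      stats::rnorm(n, 0, cfg$jitter_sd)
    inten <- truth$I * (1 + stats::rnorm(n, 0, cfg$intensity_noise_sd))
    if (!is_vcd(cfg$modality)) inten <- pmax(inten, 1e-6)
    line_spectrum(freq, inten, cfg$modality, conformer_id)
  })
}

#' Render the synthetic experimental spectrum
#'
#' Re-convolutes the truth bands on the grid and adds Gaussian baseline noise
#' scaled to the maximum band height.
#'
#' @param truth A [make_truth()] peak list.
#' @param cfg The [synthetic_config()].
#' @param grid Wavenumber grid; defaults to the config window padded by three
#'   theoretical FWHM.
#' @return A [continuous_spectrum()].
#' @export
render_experimental <- function(truth, cfg, grid = NULL) {
  if (is.null(grid)) {
    grid <- default_grid(cfg$window$lo, cfg$window$hi, cfg$theo_fwhm,
                         cfg$window$step)
  }
  base <- reconvolute(truth, grid, cfg$modality)
  with_seed(cfg$seed + 2L, {
    noise <- stats::rnorm(length(grid), 0,
                          cfg$baseline_noise_sd * max(abs(truth$I)))
    continuous_spectrum(grid, base$intensity + noise, cfg$modality)
  })
}

#' Generate decoy isomer line spectra
#'
#' Each decoy perturbs a random subset (at least 30%) of the truth bands by
#' frequency shifts of standard deviation `severity * jitter_sd` and reshuffles
#' the intensities within that subset, then passes through the same
#' systematic-scale-plus-jitter pipeline as the true spectrum. Decoys play the
#' role of incorrect diastereomers: same systematic scaling, different band
#' pattern.
#'
#' @param truth A [make_truth()] peak list.
#' @param k Number of decoys (>= 1).
#' @param severity Multiplier on `jitter_sd` for the decoy perturbation;
#'   should exceed 1 so decoys are distinguishable from noise (default 5).
#' @param cfg The [synthetic_config()].
#' @return List of `k` [line_spectrum()] objects.
#' @export
make_isomer_decoys <- function(truth, k, severity = 5, cfg) {
  stopifnot(k >= 1)
  n <- nrow(truth)
  lapply(seq_len(k), function(j) {
    perturbed <- with_seed(cfg$seed + 100L + j, {
      m <- sample(seq(ceiling(0.3 * n), n), 1)
      idx <- sort(sample(n, m))
      p <- truth
      p$x0 <- p$x0 + replace(numeric(n), idx,
                             stats::rnorm(m, 0, severity * cfg$jitter_sd))
      p$I[idx] <- p$I[sample(idx)]
      p$x0 <- pmax(p$x0, 1)
      as_peak_list(p[order(p$x0), ])
    })
    derive_theoretical(perturbed, cfg, conformer_id = paste0("decoy", j),
                       seed_offset = 200L + j)
  })
}

#' Build a complete synthetic assignment study
#'
#' Bundles one synthetic experiment (rendered spectra plus the generating
#' truths) with a true-isomer ensemble and `k_decoys` decoy ensembles, ready
#' for [screen_mu()] and [rank_isomers()]. The true isomer is named
#' `"isomer0"`.
#'
#' The default study pairs two spectroscopies, mirroring the standard
#' assignment workflow: all modalities share the same mode positions and the
#' same systematic and stochastic frequency errors (vibrational frequencies
#' are a property of the mode, not of the probe), while band heights, widths,
#' and mixing fractions are drawn independently per modality (transition
#' moments are uncorrelated between IR and Raman/VCD). Decoy perturbations
#' move the same mode subset in every modality; intensity reshuffles are
#' per-modality.
#'
#' @param cfg A [synthetic_config()]; its `modality` field is superseded by
#'   `modalities`.
#' @param k_decoys Number of decoy isomers (0 for none).
#' @param severity Decoy perturbation severity, see [make_isomer_decoys()].
#' @param modalities Modalities of the study (default IR + Raman).
#' @return List with `truth` (named list of [peak_list()] per modality),
#'   `experimental` (named list of [continuous_spectrum()]), and `ensembles`
#'   (list of [conformer_ensemble()], true isomer first).
#' @export
make_synthetic_study <- function(cfg = synthetic_config(), k_decoys = 3,
                                 severity = 5,
                                 modalities = c("IR", "RAMAN")) {
  modalities <- vapply(modalities, as_modality, character(1))
  n_mod <- length(modalities)
  cfgs <- lapply(seq_len(n_mod), function(i) {
    ci <- cfg
    ci$modality <- modalities[i]
    ## distinct baseline-noise stream per modality; same band positions below
    ci$seed <- cfg$seed + 31L * (i - 1L)
    ci
  })
  names(cfgs) <- modalities

  base <- make_truth(cfgs[[1]])
  n <- nrow(base)
  truths <- lapply(seq_len(n_mod), function(i) {
    if (i == 1L) return(base)
    with_seed(cfg$seed + 500L + i, {
      I <- stats::runif(n, 0.2, 1)
      if (is_vcd(modalities[i])) I <- I * sample(c(-1, 1), n, replace = TRUE)
      w <- stats::runif(n, cfg$exp_fwhm_range[1], cfg$exp_fwhm_range[2])
      eta <- stats::runif(n, cfg$eta_range[1], cfg$eta_range[2])
      peak_list(base$x0, I, w, eta, modalities[i], origin = "experimental")
    })
  })
  names(truths) <- modalities

  experimental <- lapply(modalities, function(m) {
    render_experimental(truths[[m]], cfgs[[m]])
  })
  names(experimental) <- modalities

  ## shared per-mode frequency error for the true isomer
  jitter <- with_seed(cfg$seed + 1L, stats::rnorm(n, 0, cfg$jitter_sd))
  theo_lines <- function(truth_x0, heights, modality, noise_seed, id) {
    inten <- with_seed(noise_seed, {
      heights * (1 + stats::rnorm(length(heights), 0, cfg$intensity_noise_sd))
    })
    if (!is_vcd(modality)) inten <- pmax(inten, 1e-6)
    line_spectrum(truth_x0 / cfg$systematic_scale + jitter, inten,
                  modality, id)
  }
  mk_ens <- function(id, spectra) {
    conformer_ensemble(id, list(list(id = "conf1", dG = 0, spectra = spectra)))
  }
  true_spectra <- lapply(seq_len(n_mod), function(i) {
    theo_lines(base$x0, truths[[i]]$I, modalities[i],
               cfg$seed + 10L + i, "conf1")
  })
  names(true_spectra) <- modalities

  ensembles <- c(list(mk_ens("isomer0", true_spectra)),
                 lapply(seq_len(k_decoys), function(j) {
    decoy <- with_seed(cfg$seed + 100L + j, {
      m <- sample(seq(ceiling(0.3 * n), n), 1)
      idx <- sort(sample(n, m))
      shifts <- replace(numeric(n), idx,
                        stats::rnorm(m, 0, severity * cfg$jitter_sd))
      x0 <- pmax(base$x0 + shifts, 1)
      heights <- lapply(truths, function(tr) {
        I <- tr$I
        I[idx] <- I[sample(idx)]
        I
      })
      list(x0 = x0, heights = heights)
    })
    dj <- with_seed(cfg$seed + 200L + j,
                    stats::rnorm(n, 0, cfg$jitter_sd))
    spectra <- lapply(seq_len(n_mod), function(i) {
      inten <- with_seed(cfg$seed + 300L + 10L * j + i, {
        decoy$heights[[i]] *
          (1 + stats::rnorm(n, 0, cfg$intensity_noise_sd))
      })
      if (!is_vcd(modalities[i])) inten <- pmax(inten, 1e-6)
      ord <- order(decoy$x0)
      line_spectrum((decoy$x0 / cfg$systematic_scale + dj)[ord], inten[ord],
                    modalities[i], paste0("decoy", j))
    })
    names(spectra) <- modalities
    mk_ens(paste0("isomer", j), spectra)
  }))
  list(truth = truths, experimental = experimental, ensembles = ensembles)
}
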