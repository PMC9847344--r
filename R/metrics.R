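#' Analysis window
#'
#' Wavenumber range and resampling step on which aligned spectra are compared.
#' The fingerprint region 1000-1500 cm^-1 is the default; spectra measured in
#' DMSO-d6 are typically restricted to 1150-1500 cm^-1 because of solvent
#' interference.
#'
#' @param lo,hi Window bounds in cm^-1, `lo < hi`.
#' @param step Resampling step in cm^-1 (default 1).
#' @return An object of class `analysis_window`.
#' @export
analysis_window <- function(lo = 1000, hi = 1500, step = 1) {
  if (lo >= hi) stop("lo must be < hi", call. = FALSE)
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  structure(list(lo = lo, hi = hi, step = step), class = "analysis_window")
}

window_grid <- function(window) seq(window$lo, window$hi, by = window$step)

#' Resample a spectrum onto an analysis window by cubic splines
#'
#' Natural cubic-spline interpolation evaluated at
#' `lo, lo + step, ..., hi`. The spectrum's grid must cover the window.
#'
#' @param spectrum A [continuous_spectrum()].
#' @param window An [analysis_window()].
#' @return A [continuous_spectrum()] on the window grid.
#' @export
resample <- function(spectrum, window) {
  x <- spectrum$wavenumber
  if (window$lo < min(x) || window$hi > max(x)) {
    stop("analysis window extends beyond the spectrum grid", call. = FALSE)
  }
  f <- stats::splinefun(x, spectrum$intensity, method = "natural")
  g <- window_grid(window)
  continuous_spectrum(g, f(g), spectrum$modality)
}

check_comparable <- function(a, b) {
  if (!isTRUE(all.equal(a$wavenumber, b$wavenumber))) {
    stop("spectra must share an identical grid", call. = FALSE)
  }
  if (stats::sd(a$intensity) == 0 || stats::sd(b$intensity) == 0) {
    stop("correlation undefined for a constant spectrum", call. = FALSE)
  }
}

#' Pearson correlation of two spectra on a common grid
#'
#' @param a,b [continuous_spectrum()]s with identical grids.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(a, b) {
  check_comparable(a, b)
  stats::cor(a$intensity, b$intensity, method = "pearson")
}

#' Spearman rank correlation of two spectra on a common grid
#'
#' Pearson correlation of the value ranks (ties by average rank); sensitive to
#' the shape rather than the scale of the spectra.
#'
#' @inheritParams pearson
#' @return Correlation coefficient in \[-1, 1\].
#' @export
spearman <- function(a, b) {
  check_comparable(a, b)
  stats::cor(a$intensity, b$intensity, method = "spearman")
}

#' Combined isomer score
#'
#' Product of the alignment score with all supplied correlation coefficients,
#' e.g. `s * rP_IR * rS_IR * rP_Raman * rS_Raman` for an IR+Raman run, or the
#' analogous product with VCD correlations. Signed: an anti-correlated VCD
#' spectrum (wrong enantiomer) makes the combined score negative.
#'
#' @param s Alignment score.
#' @param correlations Numeric vector of Pearson and Spearman coefficients,
#'   one pair per modality.
#' @return The combined score `s_comb`.
#' @export
combined_score <- function(s, correlations) {
  s * prod(correlations)
}

#' Default grid of frequency scaling factors
#'
#' 0.94 to 1.02 inclusive in steps of 0.005 (17 values), the customary
#' screening range around tabulated harmonic scaling factors.
#'
#' @return Numeric vector of scaling factors.
#' @export
default_mu_grid <- function() {
  seq(0.94, 1.02, by = 0.005)
}

## Accepts either a continuous_spectrum or list(spectrum=, peaks=) per
## modality; deconvolutes when no peak list is supplied.
prepare_experimental <- function(experimental, detection, window) {
  mods <- names(experimental)
  stopifnot(!is.null(mods), all(nzchar(mods)))
  out <- lapply(mods, function(m) {
    el <- experimental[[m]]
    if (inherits(el, "continuous_spectrum")) el <- list(spectrum = el)
    if (is.null(el$peaks)) {
      el$peaks <- deconvolute_spectrum(el$spectrum, detection,
                                       origin = "experimental")$bands
    }
    keep <- el$peaks$x0 >= window$lo & el$peaks$x0 <= window$hi
    if (!any(keep)) stop("no experimental peaks inside the analysis window",
                         call. = FALSE)
    el$peaks <- as_peak_list(el$peaks[keep, ])
    el$resampled <- resample(el$spectrum, window)
    el
  })
  names(out) <- vapply(mods, as_modality, character(1))
  out
}

#' Screen frequency scaling factors and assess one isomer
#'
#' For every scaling factor mu in the grid: the theoretical bands are scaled,
#' aligned to the experimental bands (jointly across modalities when more than
#' one is supplied), shifted onto their matched positions, re-convoluted, and
#' compared to the experimental spectrum on the analysis window via Pearson
#' and Spearman correlations. The per-mu record holds the alignment score `s`,
#' the per-modality correlations, and the combined score; the best mu is the
#' grid argmax of the combined score.
#'
#' @param experimental Named list keyed by modality. Each element is either a
#'   [continuous_spectrum()] (deconvoluted automatically) or a list with
#'   elements `spectrum` and `peaks` (a pre-fitted [peak_list()]).
#' @param ensemble A [conformer_ensemble()] for the candidate isomer.
#' @param window An [analysis_window()].
#' @param scoring A [scoring_config()]; its `mu` is ignored in favour of the
#'   grid.
#' @param shape A [band_shape()] for broadening the theoretical line spectra.
#' @param detection A [peak_detection_config()] used for any deconvolution
#'   performed here.
#' @param mu_grid Scaling factors to evaluate (default [default_mu_grid()]).
#' @return An object of class `isomer_assessment`: `isomer_id`, `table` (one
#'   row per mu: `mu`, `s`, `rP_<mod>`/`rS_<mod>` per modality, `s_comb`),
#'   `best_mu`, `best_s_comb`, and `best_pairs` (matched pairs per modality at
#'   the best mu).
#' @export
screen_mu <- function(experimental, ensemble, window = analysis_window(),
                      scoring = scoring_config(), shape = band_shape(),
                      detection = peak_detection_config(),
                      mu_grid = default_mu_grid()) {
  stopifnot(length(mu_grid) >= 1L)
  exps <- prepare_experimental(experimental, detection, window)
  mods <- names(exps)
  if (!all(mods %in% ensemble$modalities)) {
    stop("ensemble lacks modalities: ",
         paste(setdiff(mods, ensemble$modalities), collapse = ", "),
         call. = FALSE)
  }
  ## Broaden and deconvolute the theory over the analysis window widened by
  ## the scaling-factor range, so every band whose scaled position can fall
  ## inside the window at some mu is available; per mu, bands are selected by
  ## their scaled position.
  span_lo <- window$lo / max(mu_grid)
  span_hi <- window$hi / min(mu_grid)
  grid <- default_grid(span_lo, span_hi, shape$fwhm, window$step)
  theo <- lapply(mods, function(m) {
    spec <- ensemble_spectrum(ensemble, m, shape, grid)
    deconvolute_spectrum(spec, detection, default_fwhm = shape$fwhm,
                         origin = "theoretical")$bands
  })
  names(theo) <- mods

  eval_mu <- function(mu) {
    cfg <- scoring
    cfg$mu <- mu
    ## Alignment and score use only bands inside the window (scaled position),
    ## but the aligned spectrum re-convolutes the full band list — bands just
    ## outside the window still contribute their wings, shifted by the
    ## closest assigned band, exactly like unassigned in-window bands.
    sel <- lapply(theo, function(b) {
      keep <- which(mu * b$x0 >= window$lo & mu * b$x0 <= window$hi)
      if (!length(keep)) stop("no theoretical peaks inside the analysis window",
                              call. = FALSE)
      keep
    })
    theo_full <- lapply(mods, function(m) {
      b <- theo[[m]]
      b$I <- b$I / max(abs(b$I[sel[[m]]]))
      b
    })
    names(theo_full) <- mods
    theo_mu <- lapply(mods, function(m) {
      as_peak_list(theo_full[[m]][sel[[m]], ])
    })
    names(theo_mu) <- mods
    if (length(mods) > 1L) {
      ms <- align_multisource(lapply(exps, `[[`, "peaks"), theo_mu, cfg)
      s <- ms$score
      per <- ms$per_source
    } else {
      al <- align_peaks(exps[[1]]$peaks, theo_mu[[1]], cfg)
      s <- al$score
      per <- stats::setNames(list(al), mods)
    }
    cors <- lapply(mods, function(m) {
      pairs <- per[[m]]$pairs
      full <- theo_full[[m]]
      shifted <- full
      shifted$x0 <- apply_shift(mu * full$x0, sel[[m]][pairs$theo_idx],
                                exps[[m]]$peaks$x0[pairs$exp_idx])
      shifted <- as_peak_list(shifted[order(shifted$x0), ])
      aligned <- reconvolute(shifted, window_grid(window), m)
      c(rP = pearson(exps[[m]]$resampled, aligned),
        rS = spearman(exps[[m]]$resampled, aligned))
    })
    names(cors) <- mods
    list(s = s, cors = cors,
         s_comb = combined_score(s, unlist(cors, use.names = FALSE)),
         pairs = lapply(per, `[[`, "pairs"))
  }

  rows <- lapply(mu_grid, function(mu) {
    tryCatch(eval_mu(mu),
             error = function(e) {
               empty <- lapply(mods, function(m) c(rP = NA_real_,
                                                   rS = NA_real_))
               names(empty) <- mods
               list(s = NA_real_, cors = empty, s_comb = 0, pairs = NULL)
             })
  })
  tab <- data.frame(mu = mu_grid,
                    s = vapply(rows, `[[`, numeric(1), "s"))
  for (m in mods) {
    tab[[paste0("rP_", m)]] <- vapply(rows, function(r) r$cors[[m]][["rP"]],
                                      numeric(1))
    tab[[paste0("rS_", m)]] <- vapply(rows, function(r) r$cors[[m]][["rS"]],
                                      numeric(1))
  }
  tab$s_comb <- vapply(rows, `[[`, numeric(1), "s_comb")
  best <- which.max(tab$s_comb)
  structure(list(isomer_id = ensemble$isomer_id, table = tab,
                 best_mu = mu_grid[best], best_s_comb = tab$s_comb[best],
                 best_pairs = rows[[best]]$pairs, modalities = mods),
            class = "isomer_assessment")
}

#' Rank isomer assessments by combined score
#'
#' Sorts assessments in descending order of their best combined score (ties
#' broken by isomer id for stability) and reports the ratio of the best to
#' the second-best score — a descriptive confidence indicator: a ratio close
#' to one means the two best candidates fit the experiment similarly well.
#'
#' @param assessments List of [screen_mu()] results.
#' @return A list with `ranking` (data frame: `isomer`, `best_mu`,
#'   `best_s_comb`, `rank`) and `ratio` (best / second-best combined score;
#'   `NULL` for a single assessment). Ratios are reported unrounded.
#' @export
rank_isomers <- function(assessments) {
  stopifnot(length(assessments) >= 1L)
  df <- data.frame(
    isomer = vapply(assessments, `[[`, character(1), "isomer_id"),
    best_mu = vapply(assessments, `[[`, numeric(1), "best_mu"),
    best_s_comb = vapply(assessments, `[[`, numeric(1), "best_s_comb"),
    stringsAsFactors = FALSE)
  ord <- order(-df$best_s_comb, df$isomer)
  df <- df[ord, ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  ratio <- if (nrow(df) >= 2L) df$best_s_comb[1] / df$best_s_comb[2] else NULL
  list(ranking = df, ratio = ratio)
}

#' Enantiomer call from VCD correlation signs
#'
#' The alignment score is insensitive to the VCD sign, but the correlations of
#' the aligned VCD spectra are anti-correlated for the wrong enantiomer:
#' both coefficients positive indicates the computed enantiomer matches the
#' measurement, both negative indicates its mirror image, and mixed signs or
#' near-zero magnitudes give no call.
#'
#' @param vcd_r_P,vcd_r_S Pearson and Spearman coefficients of the aligned
#'   VCD spectra, in \[-1, 1\].
#' @param threshold Magnitude below which a coefficient is treated as
#'   uninformative (default 0.05).
#' @return `"correct_enantiomer"`, `"mirror_enantiomer"`, or `"ambiguous"`.
#' @export
enantiomer_sign <- function(vcd_r_P, vcd_r_S, threshold = 0.05) {
  stopifnot(abs(vcd_r_P) <= 1, abs(vcd_r_S) <= 1)
  if (abs(vcd_r_P) < threshold || abs(vcd_r_S) < threshold) return("ambiguous")
  if (vcd_r_P > 0 && vcd_r_S > 0) return("correct_enantiomer")
  if (vcd_r_P < 0 && vcd_r_S < 0) return("mirror_enantiomer")
  "ambiguous"
}

#' Flatten isomer assessments to the fixed export table
#'
#' One row per isomer x mu with the fixed column layout
#' `isomer,mu,s,rP_IR,rS_IR,rP_X,rS_X,s_comb`, where `X` is the second
#' modality of the run (Raman or VCD); the `X` columns are `NA` for
#' IR-only runs.
#'
#' @param assessments List of [screen_mu()] results.
#' @return A data frame.
#' @export
assessment_table <- function(assessments) {
  do.call(rbind, lapply(assessments, function(a) {
    other <- setdiff(a$modalities, "IR")
    out <- data.frame(isomer = a$isomer_id, mu = a$table$mu, s = a$table$s)
    out$rP_IR <- a$table[["rP_IR"]] %||% NA_real_
    out$rS_IR <- a$table[["rS_IR"]] %||% NA_real_
    out$rP_X <- if (length(other)) a$table[[paste0("rP_", other[1])]] else NA_real_
    out$rS_X <- if (length(other)) a$table[[paste0("rS_", other[1])]] else NA_real_
    out$s_comb <- a$table$s_comb
    out
  }))
}

#' @export
print.isomer_assessment <- function(x, ...) {
  cat(sprintf("<isomer_assessment> '%s': best s_comb = %.4f at mu = %.3f (%d mu values)\n",
              x$isomer_id, x$best_s_comb, x$best_mu, nrow(x$table)))
  invisible(x)
}
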