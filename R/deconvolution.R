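#' Peak-detection configuration
#'
#' @param min_prominence Minimum topographic prominence of a reported peak,
#'   as a fraction of the spectrum's maximum absolute intensity; in (0, 1).
#' @param min_separation Minimum distance between reported peaks in cm^-1.
#' @param manual_positions Optional wavenumbers that override automatic
#'   detection entirely (for noisy spectra where manual selection is needed).
#' @return An object of class `peak_detection_config`.
#' @export
peak_detection_config <- function(min_prominence = 0.02, min_separation = 4,
                                  manual_positions = NULL) {
  if (min_prominence <= 0 || min_prominence >= 1) {
    stop("min_prominence must lie in (0, 1)", call. = FALSE)
  }
  if (min_separation < 0) stop("min_separation must be >= 0", call. = FALSE)
  structure(list(min_prominence = min_prominence,
                 min_separation = min_separation,
                 manual_positions = manual_positions),
            class = "peak_detection_config")
}

## Topographic prominence of local maxima: the drop from a peak to the highest
## of the two minima separating it from higher ground (or the signal edge).
peak_prominences <- function(v, idx) {
  vapply(idx, function(i) {
    h <- v[i]
    left <- if (i > 1L) {
      seg <- v[seq_len(i - 1L)]
      higher <- which(seg > h)
      if (length(higher)) min(seg[(max(higher)):(i - 1L)]) else min(seg)
    } else h
    right <- if (i < length(v)) {
      seg <- v[(i + 1L):length(v)]
      higher <- which(seg > h)
      if (length(higher)) min(seg[1:(min(higher))]) else min(seg)
    } else h
    h - max(left, right)
  }, numeric(1))
}

#' Detect peak positions in a continuous spectrum
#'
#' Local maxima are filtered by topographic prominence relative to the
#' spectrum maximum and by a minimum mutual separation (higher peaks win).
#' For VCD the detection runs on absolute values so that negative bands are
#' found too. If `manual_positions` are supplied they are returned verbatim
#' (sorted) and must lie within the grid.
#'
#' @param spectrum A [continuous_spectrum()].
#' @param cfg A [peak_detection_config()].
#' @return Sorted numeric vector of peak wavenumbers (possibly empty).
#' @export
detect_peaks <- function(spectrum, cfg = peak_detection_config()) {
  x <- spectrum$wavenumber
  if (!is.null(cfg$manual_positions)) {
    pos <- sort(cfg$manual_positions)
    if (any(pos < min(x) | pos > max(x))) {
      stop("manual positions outside the spectrum grid", call. = FALSE)
    }
    return(pos)
  }
  v <- spectrum$intensity
  if (is_vcd(spectrum$modality)) v <- abs(v)
  n <- length(v)
  if (n < 3L) return(numeric(0))
  cand <- which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] >= v[3:n]) + 1L
  if (!length(cand)) return(numeric(0))
  prom <- peak_prominences(v, cand)
  keep <- cand[prom >= cfg$min_prominence * max(abs(v))]
  if (!length(keep)) return(numeric(0))
  ## enforce min separation greedily, highest peaks first
  keep <- keep[order(v[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in keep) {
    if (!length(sel) || all(abs(x[i] - x[sel]) >= cfg$min_separation)) {
      sel <- c(sel, i)
    }
  }
  sort(x[sel])
}

## FWHM estimate from the half-maximum crossings around a detected peak.
estimate_fwhm <- function(x, v, i, fallback = 12) {
  half <- abs(v[i]) / 2
  va <- abs(v)
  left <- right <- NA_real_
  j <- i
  while (j > 1L) {
    j <- j - 1L
    if (va[j] <= half) { left <- x[i] - x[j]; break }
    if (va[j] > va[j + 1L]) break  # climbing into a neighbour band
  }
  j <- i
  while (j < length(v)) {
    j <- j + 1L
    if (va[j] <= half) { right <- x[j] - x[i]; break }
    if (va[j] > va[j - 1L]) break
  }
  if (is.na(left) && is.na(right)) return(fallback)
  if (is.na(left)) return(2 * right)
  if (is.na(right)) return(2 * left)
  left + right
}

#' Fit a set of pseudo-Voigt bands simultaneously
#'
#' One band per initial position; all parameters (`x0`, `I`, `w`, `eta`) of
#' all bands are refined together by bounded Levenberg-Marquardt least
#' squares against the spectrum. Band positions are confined to within twice
#' the initial width estimate of their starting position, widths to
#' \[2 x grid spacing, half the window width\], and `eta` to \[0, 1\].
#' Heights are constrained positive except for VCD, where they are signed.
#'
#' @param spectrum A [continuous_spectrum()].
#' @param initial_positions Wavenumbers at which to seed bands (from
#'   [detect_peaks()] or manual selection); must lie within the grid.
#' @param default_fwhm Fallback initial width when no half-maximum crossing
#'   is found, cm^-1.
#' @param max_iter Maximum optimizer iterations.
#' @return A list of class `deconvolution` with elements `bands`
#'   (a [peak_list()] sorted by position), `residual_rms`, `converged`,
#'   and `collapsed` (logical per band: width at its lower bound with
#'   negligible height).
#' @export
fit_pseudo_voigts <- function(spectrum, initial_positions, default_fwhm = 12,
                              max_iter = 200) {
  x <- spectrum$wavenumber
  v <- spectrum$intensity
  if (length(initial_positions) < 1L) {
    stop("need at least one initial position", call. = FALSE)
  }
  if (any(initial_positions < min(x) | initial_positions > max(x))) {
    stop("initial positions outside the spectrum grid", call. = FALSE)
  }
  vcd <- is_vcd(spectrum$modality)
  spacing <- grid_spacing(spectrum)
  pos <- sort(initial_positions)
  k <- length(pos)
  idx <- vapply(pos, function(p) which.min(abs(x - p)), integer(1))
  I0 <- v[idx]
  if (!vcd) I0 <- pmax(I0, 1e-6 * max(abs(v)))
  w0 <- vapply(idx, function(i) estimate_fwhm(x, v, i, default_fwhm),
               numeric(1))
  w_min <- 2 * spacing
  w_max <- (max(x) - min(x)) / 2
  w0 <- pmin(pmax(w0, w_min), w_max)

  p0 <- c(pos, I0, w0, rep(0.5, k))
  lower <- c(pos - 2 * w0,
             if (vcd) rep(-Inf, k) else rep(1e-10 * max(abs(v)), k),
             rep(w_min, k), rep(0, k))
  upper <- c(pos + 2 * w0, rep(Inf, k), rep(w_max, k), rep(1, k))

  model <- function(p) {
    out <- numeric(length(x))
    for (i in seq_len(k)) {
      out <- out + band_value(x, p[i], p[k + i], p[2 * k + i], p[3 * k + i])
    }
    out
  }
  fit <- minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper,
    fn = function(p) model(p) - v,
    control = minpack.lm::nls.lm.control(maxiter = max_iter))
  p <- fit$par
  resid_rms <- sqrt(mean((model(p) - v)^2))
  collapsed <- abs(p[2 * k + seq_len(k)] - w_min) < 1e-9 &
    abs(p[k + seq_len(k)]) < 1e-3 * max(abs(v))
  bands <- peak_list(p[seq_len(k)], p[k + seq_len(k)], p[2 * k + seq_len(k)],
                     p[3 * k + seq_len(k)], spectrum$modality,
                     origin = "experimental")
  ord <- order(p[seq_len(k)])
  structure(list(bands = bands, residual_rms = resid_rms,
                 converged = fit$info %in% 1:4, collapsed = collapsed[ord],
                 info = fit$info),
            class = "deconvolution")
}

#' Deconvolute a spectrum: detect peaks, then fit pseudo-Voigt bands
#'
#' Convenience wrapper chaining [detect_peaks()] and [fit_pseudo_voigts()].
#' The number of fitted bands equals the number of detected peaks.
#'
#' @inheritParams detect_peaks
#' @inheritParams fit_pseudo_voigts
#' @param origin Origin label to assign to the fitted bands.
#' @return A `deconvolution` result, see [fit_pseudo_voigts()].
#' @export
deconvolute_spectrum <- function(spectrum, cfg = peak_detection_config(),
                                 default_fwhm = 12, origin = "experimental") {
  pos <- detect_peaks(spectrum, cfg)
  if (!length(pos)) {
    stop("no peaks detected; lower min_prominence or supply manual positions",
         call. = FALSE)
  }
  res <- fit_pseudo_voigts(spectrum, pos, default_fwhm = default_fwhm)
  res$bands$origin <- origin
  res
}

#' Re-convolute a peak list into a continuous spectrum
#'
#' Pointwise sum of all pseudo-Voigt bands (per-band width and mixing) on a
#' grid. An empty band list yields the zero spectrum.
#'
#' @param bands A [peak_list()] (or an empty data frame).
#' @param grid Ascending wavenumber grid.
#' @param modality Modality of the result; defaults to the bands' modality.
#' @return A [continuous_spectrum()].
#' @export
reconvolute <- function(bands, grid, modality = NULL) {
  if (is.null(modality)) {
    modality <- if (nrow(bands)) bands$modality[1] else "IR"
  }
  vals <- numeric(length(grid))
  for (i in seq_len(nrow(bands))) {
    vals <- vals + band_value(grid, bands$x0[i], bands$I[i], bands$w[i],
                              bands$eta[i])
  }
  continuous_spectrum(grid, vals, modality)
}

#' @export
print.deconvolution <- function(x, ...) {
  cat(sprintf("<deconvolution> %d band(s), residual RMS %.3g, %s\n",
              nrow(x$bands), x$residual_rms,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
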