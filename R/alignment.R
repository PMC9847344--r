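#' Scoring configuration for peak alignment
#'
#' @param mu Frequency scaling factor applied once to theoretical peak
#'   positions, before scoring and before cutoff evaluation; corrects the
#'   systematic error of the harmonic approximation.
#' @param C_nu Cutoff for the frequency difference, cm^-1. Two peaks further
#'   apart than this (after scaling) can never be matched.
#' @param C_I Cutoff for the intensity difference on max-normalized
#'   intensities (dimensionless).
#' @param C_w Cutoff for the bandwidth difference, cm^-1.
#' @param gap_score Score contribution of a gap (default 0: gaps are free but
#'   unrewarded; the cutoffs already prevent bad matches).
#' @param normalize_score If `TRUE` (default) the optimal raw score is divided
#'   by `max(n_exp, n_theo)` so that the total lies in \[0, 1\] and is
#'   comparable across isomers with different peak counts.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(mu = 1, C_nu = 30, C_I = 0.5, C_w = 20,
                           gap_score = 0, normalize_score = TRUE) {
  if (mu <= 0) stop("mu must be > 0", call. = FALSE)
  if (C_nu <= 0 || C_I <= 0 || C_w <= 0) {
    stop("all cutoffs must be > 0", call. = FALSE)
  }
  structure(list(mu = mu, C_nu = C_nu, C_I = C_I, C_w = C_w,
                 gap_score = gap_score, normalize_score = normalize_score),
            class = "scoring_config")
}

#' Legacy scoring configuration
#'
#' Parameters of the older two-term Gaussian score kept for backward
#' comparison; `sigma1` and `sigma2` are spread parameters for the intensity
#' and frequency terms, fitted per computational method.
#'
#' @param sigma1,sigma2 Positive spreads of the intensity and frequency terms.
#' @param mu Frequency scaling factor.
#' @return An object of class `legacy_scoring_config`.
#' @export
legacy_scoring_config <- function(sigma1, sigma2, mu = 1) {
  if (sigma1 <= 0 || sigma2 <= 0) stop("sigmas must be > 0", call. = FALSE)
  structure(list(sigma1 = sigma1, sigma2 = sigma2, mu = mu),
            class = "legacy_scoring_config")
}

#' Normalize peak intensities to unit maximum magnitude
#'
#' Divides all intensities by the maximum absolute intensity in the list, so
#' max |I| = 1. Signs (VCD) are preserved; positions and widths unchanged.
#' Required because measured absorbances and computed intensities live on
#' unrelated scales.
#'
#' @param peaks A [peak_list()].
#' @return The normalized [peak_list()].
#' @export
normalize_intensities <- function(peaks) {
  stopifnot(nrow(peaks) >= 1L)
  m <- max(abs(peaks$I))
  if (m == 0) stop("cannot normalize an all-zero intensity list", call. = FALSE)
  peaks$I <- peaks$I / m
  peaks
}

#' Smooth compactly supported score kernel (mollifier)
#'
#' `exp(1 - 1 / (1 - (delta/cutoff)^2))` for `|delta| < cutoff`, else 0:
#' equal to 1 at `delta = 0`, exactly 0 at and beyond the cutoff, infinitely
#' differentiable, and strictly decreasing in `|delta|` on the support.
#'
#' @param delta Difference(s) between an experimental and a theoretical peak
#'   attribute.
#' @param cutoff Positive cutoff in the same units as `delta`.
#' @return Score value(s) in \[0, 1\].
#' @export
mollifier <- function(delta, cutoff) {
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  u2 <- (delta / cutoff)^2
  out <- numeric(length(u2))
  inside <- u2 < 1
  out[inside] <- exp(1 - 1 / (1 - u2[inside]))
  out
}

#' Score one experimental/theoretical peak pair
#'
#' Product of three mollifier components: frequency
#' `mollifier(nu_e - mu * nu_t, C_nu)`, intensity
#' `mollifier(|I_e| - |I_t|, C_I)`, and bandwidth
#' `mollifier(w_e - w_t, C_w)`. The score is 1 for identical peaks and 0 as
#' soon as any component is 0, so a high-intensity peak can never be matched
#' to a low-intensity peak even at similar frequencies. VCD signs are ignored
#' here (magnitudes compared); the sign enters only through the correlation
#' metrics.
#'
#' @param exp_peak,theo_peak Single-row [peak_list()]s (or lists with `x0`,
#'   `I`, `w`), intensity-normalized within their lists.
#' @param cfg A [scoring_config()]; `cfg$mu` is applied to the theoretical
#'   position here (exactly once in the pipeline).
#' @return Score in \[0, 1\].
#' @export
pair_score <- function(exp_peak, theo_peak, cfg = scoring_config()) {
  mollifier(exp_peak$x0 - cfg$mu * theo_peak$x0, cfg$C_nu) *
    mollifier(abs(exp_peak$I) - abs(theo_peak$I), cfg$C_I) *
    mollifier(exp_peak$w - theo_peak$w, cfg$C_w)
}

#' Legacy two-term pair score
#'
#' Older score kept for backward comparison: a product of a Gaussian intensity
#' term and a Gaussian frequency term,
#' `exp(-(I_e - I_t)^2 / sigma1^2) * exp(-(nu_e - mu*nu_t)^2 / sigma2^2)`.
#' Its maximum is 1 at identical peaks but it reaches zero only at infinite
#' frequency separation — the defect the mollifier score removes.
#'
#' @inheritParams pair_score
#' @param cfg A [legacy_scoring_config()].
#' @return Score in (0, 1\].
#' @export
legacy_pair_score <- function(exp_peak, theo_peak, cfg) {
  stopifnot(inherits(cfg, "legacy_scoring_config"))
  exp(-(exp_peak$I - theo_peak$I)^2 / cfg$sigma1^2) *
    exp(-(exp_peak$x0 - cfg$mu * theo_peak$x0)^2 / cfg$sigma2^2)
}

## Global DP over a pairwise score matrix (rows = experimental peaks, cols =
## theoretical peaks). -Inf entries forbid the match. Traceback ties are broken
## deterministically: match > theoretical gap > experimental gap.
dp_align <- function(S, gap = 0) {
  ne <- nrow(S)
  nt <- ncol(S)
  M <- matrix(0, ne + 1L, nt + 1L)
  M[, 1] <- gap * (0:ne)
  M[1, ] <- gap * (0:nt)
  for (i in seq_len(ne)) {
    for (j in seq_len(nt)) {
      diag <- if (is.finite(S[i, j])) M[i, j] + S[i, j] else -Inf
      M[i + 1L, j + 1L] <- max(diag, M[i + 1L, j] + gap, M[i, j + 1L] + gap)
    }
  }
  pairs <- matrix(integer(0), 0, 2)
  i <- ne; j <- nt
  while (i > 0L && j > 0L) {
    here <- M[i + 1L, j + 1L]
    if (is.finite(S[i, j]) && here == M[i, j] + S[i, j]) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1L; j <- j - 1L
    } else if (here == M[i + 1L, j] + gap) {
      j <- j - 1L                       # theoretical gap
    } else {
      i <- i - 1L                       # experimental gap
    }
  }
  list(pairs = pairs, total = M[ne + 1L, nt + 1L])
}

make_alignment <- function(pairs, scores, ne, nt, raw, cfg,
                           exp_x0 = NULL, theo_x0 = NULL) {
  keep <- scores > 0
  pairs <- pairs[keep, , drop = FALSE]
  scores <- scores[keep]
  pdf <- data.frame(exp_idx = pairs[, 1], theo_idx = pairs[, 2],
                    score = scores)
  if (!is.null(exp_x0)) pdf$exp_x0 <- exp_x0[pdf$exp_idx]
  if (!is.null(theo_x0)) pdf$theo_x0 <- theo_x0[pdf$theo_idx]
  s <- if (isTRUE(cfg$normalize_score)) raw / max(ne, nt) else raw
  structure(list(pairs = pdf,
                 exp_gaps = setdiff(seq_len(ne), pdf$exp_idx),
                 theo_gaps = setdiff(seq_len(nt), pdf$theo_idx),
                 n_exp = ne, n_theo = nt, raw_score = raw, score = s,
                 config = cfg),
            class = "alignment")
}

#' Optimally align theoretical to experimental peaks
#'
#' Global dynamic programming (Needleman-Wunsch style) over all monotone
#' matchings of the two peak lists, maximizing the sum of [pair_score()]s
#' plus `gap_score` per unmatched peak. Peak order is strictly preserved on
#' both sides. Matches whose pair score is zero are recorded as gaps. With
#' `normalize_score` the total is divided by `max(n_exp, n_theo)`, so a score
#' of 1 means every peak matched perfectly.
#'
#' @param exp_peaks,theo_peaks [peak_list()]s sorted by position (enforced by
#'   the constructor). Intensities are max-normalized internally (idempotent).
#' @param cfg A [scoring_config()].
#' @return An object of class `alignment` with elements `pairs` (data frame
#'   of matched index pairs with positions and per-pair scores), `exp_gaps`,
#'   `theo_gaps`, `raw_score`, `score`, and a `config` echo.
#' @export
align_peaks <- function(exp_peaks, theo_peaks, cfg = scoring_config()) {
  if (nrow(exp_peaks) == 0L || nrow(theo_peaks) == 0L) {
    stop("cannot align empty peak lists", call. = FALSE)
  }
  e <- normalize_intensities(exp_peaks)
  t <- normalize_intensities(theo_peaks)
  tx <- cfg$mu * t$x0
  S <- outer(e$x0, tx, function(a, b) mollifier(a - b, cfg$C_nu)) *
    outer(abs(e$I), abs(t$I), function(a, b) mollifier(a - b, cfg$C_I)) *
    outer(e$w, t$w, function(a, b) mollifier(a - b, cfg$C_w))
  res <- dp_align(S, cfg$gap_score)
  scores <- if (nrow(res$pairs)) S[res$pairs] else numeric(0)
  make_alignment(res$pairs, scores, nrow(e), nrow(t), res$total, cfg,
                 exp_x0 = e$x0, theo_x0 = tx)
}

## Closest-assigned-peak shift rule on raw positions: matched positions snap
## to their targets; every other position moves by the displacement of the
## nearest matched position (ties to the lower-frequency neighbour).
apply_shift <- function(x0, matched_idx, targets) {
  if (!length(matched_idx)) return(x0)
  new_x0 <- x0
  new_x0[matched_idx] <- targets
  delta <- targets - x0[matched_idx]
  for (k in setdiff(seq_along(x0), matched_idx)) {
    d <- abs(x0[k] - x0[matched_idx])
    best <- which(d == min(d))
    if (length(best) > 1L) best <- best[which.min(x0[matched_idx][best])]
    new_x0[k] <- x0[k] + delta[best]
  }
  new_x0
}

#' Shift theoretical bands onto their matched experimental positions
#'
#' Matched theoretical bands take the position of their experimental partner;
#' unmatched bands are shifted by the same distance as the closest (by
#' position difference, ties to the lower-frequency neighbour) matched
#' theoretical band. Heights, widths, and mixing parameters are preserved, so
#' re-convoluting the shifted list gives the aligned theoretical spectrum
#' without inflating overlapping intensities.
#'
#' @param theo_peaks The theoretical [peak_list()] that was aligned
#'   (unscaled; the alignment's `mu` is re-applied here, once).
#' @param alignment The [align_peaks()] result for these lists.
#' @param exp_peaks The experimental [peak_list()] that was aligned.
#' @return The shifted theoretical [peak_list()], re-sorted by position. If
#'   the alignment has no matches the list is returned unshifted (apart from
#'   the mu scaling) with attribute `identity_shift = TRUE`.
#' @export
shift_theoretical <- function(theo_peaks, alignment, exp_peaks) {
  mu <- alignment$config$mu
  out <- theo_peaks
  out$x0 <- mu * out$x0
  if (nrow(alignment$pairs) == 0L) {
    attr(out, "identity_shift") <- TRUE
    return(as_peak_list(out[order(out$x0), ]))
  }
  out$x0 <- apply_shift(out$x0, alignment$pairs$theo_idx,
                        exp_peaks$x0[alignment$pairs$exp_idx])
  as_peak_list(out[order(out$x0), ])
}

#' Align peak lists from several spectroscopies simultaneously
#'
#' The per-source peak lists (each max-normalized independently) are
#' concatenated with their source label attached, sorted by frequency, and
#' aligned in one dynamic program in which a match between peaks of different
#' sources is forbidden (score `-Inf`). The source labels then split the
#' concatenated alignment back into per-source alignments. The combined score
#' is the raw optimum divided by `max(total n_exp, total n_theo)`.
#'
#' @param exp_by_source,theo_by_source Named lists of [peak_list()]s keyed by
#'   modality; the two sides must provide the same modalities.
#' @param cfg A [scoring_config()].
#' @return A list of class `multisource_alignment` with elements `per_source`
#'   (named list of [align_peaks()]-style alignments with per-source indices),
#'   `score` (combined normalized score), and `raw_score`.
#' @export
align_multisource <- function(exp_by_source, theo_by_source,
                              cfg = scoring_config()) {
  mods <- sort(names(exp_by_source))
  if (!identical(mods, sort(names(theo_by_source)))) {
    stop("experimental and theoretical sides must share the same modalities",
         call. = FALSE)
  }
  ## Sort by frequency, but order cross-source near-ties (the same normal
  ## mode seen by both spectroscopies, whose fitted positions differ only by
  ## fit noise) canonically by modality on both sides. Otherwise noise in the
  ## sub-resolution ordering fabricates crossings that the monotonicity
  ## constraint resolves by sacrificing a genuine match.
  tie_tol <- 2
  cat_side <- function(lists, scale) {
    parts <- lapply(mods, function(m) {
      p <- normalize_intensities(lists[[m]])
      data.frame(x0 = scale * p$x0, I = p$I, w = p$w, eta = p$eta,
                 source = m, local = seq_len(nrow(p)))
    })
    df <- do.call(rbind, parts)
    df <- df[order(df$x0), ]
    repeat {
      swapped <- FALSE
      for (i in seq_len(nrow(df) - 1L)) {
        if (df$x0[i + 1L] - df$x0[i] < tie_tol &&
            df$source[i] > df$source[i + 1L]) {
          df[c(i, i + 1L), ] <- df[c(i + 1L, i), ]
          swapped <- TRUE
        }
      }
      if (!swapped) break
    }
    df
  }
  e <- cat_side(exp_by_source, 1)
  t <- cat_side(theo_by_source, cfg$mu)
  S <- outer(e$x0, t$x0, function(a, b) mollifier(a - b, cfg$C_nu)) *
    outer(abs(e$I), abs(t$I), function(a, b) mollifier(a - b, cfg$C_I)) *
    outer(e$w, t$w, function(a, b) mollifier(a - b, cfg$C_w))
  S[outer(e$source, t$source, `!=`)] <- -Inf
  res <- dp_align(S, cfg$gap_score)
  scores <- if (nrow(res$pairs)) S[res$pairs] else numeric(0)
  keep <- scores > 0
  pairs <- res$pairs[keep, , drop = FALSE]
  scores <- scores[keep]

  per_source <- lapply(mods, function(m) {
    ei <- which(e$source == m)
    ti <- which(t$source == m)
    in_src <- pairs[, 1] %in% ei           # matched pairs never cross sources
    sp <- pairs[in_src, , drop = FALSE]
    loc <- cbind(e$local[sp[, 1]], t$local[sp[, 2]])
    raw_src <- sum(scores[in_src]) +
      cfg$gap_score * (length(ei) + length(ti) - 2 * nrow(sp))
    make_alignment(loc, scores[in_src], length(ei), length(ti), raw_src, cfg,
                   exp_x0 = e$x0[ei][order(e$local[ei])],
                   theo_x0 = t$x0[ti][order(t$local[ti])])
  })
  names(per_source) <- mods
  s <- if (isTRUE(cfg$normalize_score)) {
    res$total / max(nrow(e), nrow(t))
  } else {
    res$total
  }
  structure(list(per_source = per_source, score = s, raw_score = res$total,
                 config = cfg),
            class = "multisource_alignment")
}

#' Export an alignment as JSON
#'
#' @param alignment An [align_peaks()] result.
#' @param path Output path.
#' @export
write_alignment_json <- function(alignment, path) {
  jsonlite::write_json(unclass(alignment), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d/%d exp and %d/%d theo peaks matched, s = %.4f\n",
              nrow(x$pairs), x$n_exp, nrow(x$pairs), x$n_theo, x$score))
  invisible(x)
}

#' @export
print.multisource_alignment <- function(x, ...) {
  cat(sprintf("<multisource_alignment> sources %s, combined s = %.4f\n",
              paste(names(x$per_source), collapse = "+"), x$score))
  invisible(x)
}
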