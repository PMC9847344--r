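#' @keywords internal
"_PACKAGE"

## Recognized spectroscopic modalities. Every spectrum and every peak carries
## exactly one of these labels; it doubles as the source index in multi-source
## alignment.
MODALITIES <- c("IR", "RAMAN", "VCD")

#' Validate a modality label
#'
#' @param modality Character scalar, one of `"IR"`, `"RAMAN"`, `"VCD"`
#'   (case-insensitive).
#' @return The canonical upper-case label.
#' @export
as_modality <- function(modality) {
  stopifnot(is.character(modality), length(modality) == 1L)
  m <- toupper(modality)
  if (!m %in% MODALITIES) {
    stop("unknown modality '", modality, "'; expected one of ",
         paste(MODALITIES, collapse = ", "), call. = FALSE)
  }
  m
}

is_vcd <- function(modality) identical(as_modality(modality), "VCD")

#' Construct a line (stick) spectrum
#'
#' A line spectrum is the set of discrete (wavenumber, intensity) pairs of a
#' harmonic frequency calculation for one conformer, before any broadening.
#'
#' @param wavenumber Numeric vector of positions in cm^-1, strictly increasing
#'   after sorting; duplicates are not allowed.
#' @param intensity Numeric vector of line intensities (arbitrary units).
#'   Must be non-negative for IR and Raman; VCD lines may be negative.
#' @param modality Modality label, see [as_modality()].
#' @param conformer_id Identifier of the conformer the lines belong to.
#' @return An object of class `line_spectrum`.
#' @export
line_spectrum <- function(wavenumber, intensity, modality = "IR",
                          conformer_id = "conf1") {
  modality <- as_modality(modality)
  stopifnot(is.numeric(wavenumber), is.numeric(intensity),
            length(wavenumber) == length(intensity))
  if (any(!is.finite(wavenumber)) || any(!is.finite(intensity))) {
    stop("line spectrum contains non-finite values", call. = FALSE)
  }
  if (any(wavenumber <= 0)) stop("wavenumbers must be positive", call. = FALSE)
  ord <- order(wavenumber)
  wavenumber <- wavenumber[ord]
  intensity <- intensity[ord]
  if (anyDuplicated(wavenumber)) {
    stop("wavenumbers must be strictly increasing (duplicates found)",
         call. = FALSE)
  }
  if (!is_vcd(modality) && any(intensity < 0)) {
    stop("negative intensities are only allowed for VCD line spectra",
         call. = FALSE)
  }
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 modality = modality, conformer_id = conformer_id),
            class = "line_spectrum")
}

#' Construct a continuous spectrum on a uniform wavenumber grid
#'
#' @param wavenumber Strictly increasing, uniformly spaced grid in cm^-1.
#' @param intensity Intensity at each grid point.
#' @param modality Modality label.
#' @return An object of class `continuous_spectrum`.
#' @export
continuous_spectrum <- function(wavenumber, intensity, modality = "IR") {
  modality <- as_modality(modality)
  stopifnot(is.numeric(wavenumber), is.numeric(intensity),
            length(wavenumber) == length(intensity), length(wavenumber) >= 2L)
  d <- diff(wavenumber)
  if (any(d <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  if (max(d) - min(d) > 1e-6 * stats::median(d)) {
    stop("grid must be uniformly spaced; resample first", call. = FALSE)
  }
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 modality = modality),
            class = "continuous_spectrum")
}

grid_spacing <- function(spectrum) {
  stats::median(diff(spectrum$wavenumber))
}

#' Construct a peak list of pseudo-Voigt bands
#'
#' A peak list is an ordered collection of pseudo-Voigt bands, each with a
#' position `x0` (cm^-1), height `I` (signed only for VCD), full width at half
#' maximum `w` (cm^-1), and Lorentzian mixing fraction `eta` in \[0, 1\].
#' All bands in a list share the same origin (experimental or theoretical).
#'
#' @param x0,I,w,eta Numeric vectors of equal length: position, height, FWHM,
#'   and mixing parameter of each band.
#' @param modality Modality label for every band, or a vector of labels.
#' @param origin `"experimental"` or `"theoretical"` (one value for the list).
#' @return A data frame of class `peak_list` with columns
#'   `x0, I, w, eta, modality, origin`, ordered by non-decreasing `x0`.
#' @export
peak_list <- function(x0, I, w, eta = 0.5, modality = "IR",
                      origin = "experimental") {
  n <- length(x0)
  stopifnot(n >= 1L, length(I) == n, length(w) == n)
  eta <- rep_len(eta, n)
  modality <- vapply(rep_len(modality, n), as_modality, character(1))
  origin <- match.arg(origin, c("experimental", "theoretical"))
  if (any(w <= 0)) stop("bandwidths w must be > 0", call. = FALSE)
  if (any(eta < 0 | eta > 1)) stop("eta must lie in [0, 1]", call. = FALSE)
  bad <- modality != "VCD" & I <= 0
  if (any(bad)) {
    stop("IR/Raman band heights must be > 0 (", sum(bad), " offending bands)",
         call. = FALSE)
  }
  ord <- order(x0)
  out <- data.frame(x0 = x0[ord], I = I[ord], w = w[ord], eta = eta[ord],
                    modality = modality[ord], origin = origin,
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_list", "data.frame")
  out
}

## Re-assert peak_list class after data.frame subsetting stripped it.
as_peak_list <- function(df) {
  stopifnot(all(c("x0", "I", "w", "eta", "modality", "origin") %in% names(df)))
  rownames(df) <- NULL
  class(df) <- c("peak_list", "data.frame")
  df
}

#' Construct a conformer ensemble
#'
#' Bundles the per-conformer line spectra of one candidate isomer with the
#' conformers' relative (free) energies. Energies are shifted so their minimum
#' is zero; Boltzmann weights are invariant under this shift.
#'
#' @param isomer_id Identifier of the isomer.
#' @param conformers List of conformers, each a list with elements `id`,
#'   `dG` (kcal/mol, may be missing for a single conformer), and `spectra`,
#'   a named list of [line_spectrum()] objects keyed by modality.
#' @param temperature Temperature in kelvin used for Boltzmann weighting.
#' @return An object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(isomer_id, conformers, temperature = 298.15) {
  stopifnot(length(conformers) >= 1L, temperature > 0)
  dG <- vapply(conformers, function(cf) {
    if (is.null(cf$dG) || is.na(cf$dG)) 0 else as.numeric(cf$dG)
  }, numeric(1))
  dG <- dG - min(dG)
  mods <- lapply(conformers, function(cf) sort(names(cf$spectra)))
  if (length(unique(mods)) != 1L) {
    stop("all conformers must provide the same set of modalities",
         call. = FALSE)
  }
  conformers <- Map(function(cf, g) {
    cf$dG <- g
    cf
  }, conformers, dG)
  structure(list(isomer_id = isomer_id, conformers = conformers,
                 temperature = temperature, modalities = mods[[1]]),
            class = "conformer_ensemble")
}

#' Read a continuous spectrum from a two-column text file
#'
#' Accepts whitespace- or comma-delimited numeric text with `#` comment lines.
#' Rows are sorted to ascending wavenumber. If the input spacing is not
#' uniform, the spectrum is linearly interpolated onto a uniform grid with the
#' median input spacing, so that downstream code may assume uniform grids.
#'
#' @param path Path to the file.
#' @param modality Modality label of the data.
#' @return A [continuous_spectrum()].
#' @export
read_continuous_spectrum <- function(path, modality = "IR") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- lines[keep]
  rownos <- which(keep)
  if (length(rows) < 4L) {
    stop("insufficient data: need at least 4 data rows, got ", length(rows),
         call. = FALSE)
  }
  parsed <- lapply(seq_along(rows), function(i) {
    fields <- strsplit(trimws(rows[[i]]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || anyNA(vals[1:2])) {
      stop("parse error at line ", rownos[i], " of ", path,
           ": expected two numeric columns", call. = FALSE)
    }
    vals[1:2]
  })
  m <- do.call(rbind, parsed)
  ord <- order(m[, 1])
  x <- m[ord, 1]
  y <- m[ord, 2]
  d <- diff(x)
  if (any(d <= 0)) stop("duplicate wavenumbers in ", path, call. = FALSE)
  if (max(d) - min(d) > 1e-6 * stats::median(d)) {
    step <- stats::median(d)
    grid <- seq(x[1], x[length(x)], by = step)
    y <- stats::approx(x, y, xout = grid)$y
    x <- grid
  }
  continuous_spectrum(x, y, modality)
}

#' Write a continuous spectrum as two-column text
#'
#' @param spectrum A [continuous_spectrum()].
#' @param path Output path.
#' @export
write_continuous_spectrum <- function(spectrum, path) {
  header <- sprintf("# modality: %s", spectrum$modality)
  body <- sprintf("%.8g %.8g", spectrum$wavenumber, spectrum$intensity)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a conformer ensemble from JSON
#'
#' Expects the ensemble JSON layout written by [write_line_spectra()]:
#' `{isomer_id, temperature, conformers: [{id, dG_kcal_mol,
#' modalities: {IR: [[freq, inten], ...], ...}}]}`. A missing `dG_kcal_mol`
#' defaults to 0; energies are min-shifted on construction.
#'
#' @param path Path to the JSON file.
#' @return A [conformer_ensemble()].
#' @export
read_line_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$isomer_id) || is.null(raw$conformers)) {
    stop("ensemble JSON must contain 'isomer_id' and 'conformers'",
         call. = FALSE)
  }
  temperature <- if (is.null(raw$temperature)) 298.15 else raw$temperature
  conformers <- lapply(raw$conformers, function(cf) {
    spectra <- lapply(names(cf$modalities), function(mod) {
      tab <- do.call(rbind, lapply(cf$modalities[[mod]], unlist))
      line_spectrum(tab[, 1], tab[, 2], modality = mod,
                    conformer_id = cf$id %||% "conf")
    })
    names(spectra) <- vapply(spectra, `[[`, character(1), "modality")
    list(id = cf$id %||% "conf", dG = cf$dG_kcal_mol %||% 0, spectra = spectra)
  })
  conformer_ensemble(raw$isomer_id, conformers, temperature)
}

#' Write a conformer ensemble to JSON
#'
#' @param ensemble A [conformer_ensemble()].
#' @param path Output path.
#' @export
write_line_spectra <- function(ensemble, path) {
  conformers <- lapply(ensemble$conformers, function(cf) {
    mods <- lapply(cf$spectra, function(ls) {
      lapply(seq_along(ls$wavenumber),
             function(i) c(ls$wavenumber[i], ls$intensity[i]))
    })
    list(id = cf$id, dG_kcal_mol = cf$dG, modalities = mods)
  })
  jsonlite::write_json(
    list(isomer_id = ensemble$isomer_id, temperature = ensemble$temperature,
         conformers = conformers),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a peak list as CSV
#'
#' The CSV has the fixed header `x0,I,w,eta,modality,origin`.
#'
#' @param path File path.
#' @return [read_peak_list()] returns a [peak_list()].
#' @export
read_peak_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  peak_list(df$x0, df$I, df$w, df$eta, df$modality, unique(df$origin))
}

#' @param peaks A [peak_list()].
#' @rdname read_peak_list
#' @export
write_peak_list <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks), path, row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable assessment report
#'
#' Serializes per-isomer, per-mu metrics together with the matched peak pairs
#' of the best alignment, plus a ranked summary with the best/second-best
#' combined-score ratio.
#'
#' @param assessments List of isomer assessments from [screen_mu()].
#' @param path Output JSON path.
#' @return The ranking data frame, invisibly.
#' @export
write_alignment_report <- function(assessments, path) {
  stopifnot(length(assessments) >= 1L)
  ranking <- rank_isomers(assessments)
  entries <- lapply(assessments, function(a) {
    list(isomer_id = a$isomer_id,
         best_mu = a$best_mu,
         best_s_comb = a$best_s_comb,
         metrics = a$table,
         best_pairs = a$best_pairs)
  })
  jsonlite::write_json(list(isomers = entries, ranking = ranking),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(ranking)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.continuous_spectrum <- function(x, ...) {
  cat(sprintf("<continuous_spectrum> %s, %d points, %.1f-%.1f cm-1 (step %.3g)\n",
              x$modality, length(x$wavenumber), min(x$wavenumber),
              max(x$wavenumber), grid_spacing(x)))
  invisible(x)
}

#' @export
print.line_spectrum <- function(x, ...) {
  cat(sprintf("<line_spectrum> %s '%s', %d lines in %.1f-%.1f cm-1\n",
              x$modality, x$conformer_id, length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> '%s': %d conformer(s), modalities %s, T = %.2f K\n",
              x$isomer_id, length(x$conformers),
              paste(x$modalities, collapse = "+"), x$temperature))
  invisible(x)
}
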