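## Far-UV circular dichroism analytics: mean-residue ellipticity conversion,
## the theta222/theta208 coiled-coil ratio, spectral-shape classification and
## non-negative basis deconvolution.

#' Convert machine ellipticity to mean residue ellipticity
#'
#' Applies the standard conversion from raw instrument ellipticity
#' (millidegrees) to mean residue ellipticity (MRE),
#' \deqn{[\theta] = \theta_{mdeg} / (10 \, l \, c \, n)}
#' with path length \eqn{l} in cm, molar protein concentration \eqn{c} and
#' \eqn{n} peptide-bond residues; units deg cm^2 dmol^-1.
#'
#' @param spectrum A tibble with columns `wavelength` (nm) and `ellipticity`
#'   (raw, millidegrees).
#' @param path_length_cm Cuvette path length in cm (e.g. 0.01 for 0.1 mm).
#' @param concentration_m Protein concentration in mol/L.
#' @param n_residues Number of residues.
#' @return A tibble with columns `wavelength`, `ellipticity` (now MRE,
#'   deg cm^2 dmol^-1).
#' @export
to_mean_residue_ellipticity <- function(spectrum, path_length_cm,
                                        concentration_m, n_residues) {
  check_spectrum(spectrum)
  if (path_length_cm <= 0 || concentration_m <= 0 || n_residues <= 0) {
    abort("path length, concentration and residue count must be positive")
  }
  dplyr::mutate(spectrum, ellipticity = .data$ellipticity /
                  (10 * path_length_cm * concentration_m * n_residues))
}

check_spectrum <- function(spectrum, require_range = NULL) {
  stopifnot(is.data.frame(spectrum),
            all(c("wavelength", "ellipticity") %in% names(spectrum)))
  wl <- spectrum$wavelength
  if (length(wl) < 2L || any(diff(wl) <= 0)) {
    abort("spectrum wavelengths must be strictly increasing (>= 2 points)")
  }
  if (anyNA(spectrum$ellipticity) || any(!is.finite(spectrum$ellipticity))) {
    abort("spectrum ellipticity must be finite")
  }
  if (!is.null(require_range) &&
      (min(wl) > require_range[1] || max(wl) < require_range[2])) {
    abort(paste0("spectrum grid must cover ", require_range[1], "-",
                 require_range[2], " nm"))
  }
  invisible(TRUE)
}

#' Coiled-coil ratio diagnostic (theta222/theta208)
#'
#' Reads the mean residue ellipticity at 208 and 222 nm (linear
#' interpolation on the grid) and reports their ratio, the classic
#' diagnostic for coiled-coil formation in helical proteins: a ratio
#' strictly greater than 1 indicates well-defined coiled coils, lower
#' values isolated helices. The ratio is only computed when both
#' ellipticities are negative (helix-like minima present); otherwise the
#' classification is `"other"` and the ratio is `NA`.
#'
#' @param spectrum A tibble with columns `wavelength` (nm, covering
#'   208-222) and `ellipticity` (MRE).
#' @return A one-row tibble: `theta208`, `theta222`, `ratio`,
#'   `classification` (`"coiled_coil"`, `"isolated_helices"` or `"other"`).
#' @examples
#' s <- synthetic_helix_spectrum(depth208 = -10, depth222 = -9.6)
#' helix_ratio(s)
#' @export
helix_ratio <- function(spectrum) {
  check_spectrum(spectrum, require_range = c(208, 222))
  th208 <- approx(spectrum$wavelength, spectrum$ellipticity, xout = 208)$y
  th222 <- approx(spectrum$wavelength, spectrum$ellipticity, xout = 222)$y
  if (th208 < 0 && th222 < 0) {
    ratio <- th222 / th208
    cls <- if (ratio > 1) "coiled_coil" else "isolated_helices"
  } else {
    ratio <- NA_real_
    cls <- "other"
  }
  tibble(theta208 = th208, theta222 = th222, ratio = ratio,
         classification = cls)
}

#' Classify the far-UV spectral shape ('w' vs 'v')
#'
#' Detects interior local minima after a light moving-average smoothing and
#' classifies the spectrum: `"w_shaped"` when two distinct minima fall in
#' the 206-212 and 218-226 nm bands (the alpha-helical double trough),
#' `"v_shaped"` when a single minimum falls in 215-222 nm (beta-rich single
#' trough), `"other"` otherwise.
#'
#' @param spectrum A tibble with `wavelength` covering 205-235 nm and
#'   `ellipticity`.
#' @param smooth_width Odd moving-average width in grid points (default 3).
#' @return A one-row tibble: `shape`, `minima` (list-column of minima
#'   wavelengths).
#' @export
classify_shape <- function(spectrum, smooth_width = 3L) {
  check_spectrum(spectrum, require_range = c(205, 235))
  y <- spectrum$ellipticity
  if (smooth_width > 1L) {
    y <- as.numeric(stats::filter(y, rep(1 / smooth_width, smooth_width),
                                  sides = 2))
  }
  wl <- spectrum$wavelength
  idx <- which(!is.na(y))
  y <- y[idx]; wl <- wl[idx]
  n <- length(y)
  is_min <- c(FALSE, y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] < y[3:n],
              FALSE)
  minima <- wl[is_min]
  in_band <- function(lo, hi) any(minima >= lo & minima <= hi)
  shape <- if (in_band(206, 212) && in_band(218, 226)) {
    "w_shaped"
  } else if (length(minima) >= 1L && in_band(215, 222) &&
             sum(minima >= 205 & minima <= 235) == 1L) {
    "v_shaped"
  } else {
    "other"
  }
  tibble(shape = shape, minima = list(minima))
}

#' Synthetic helical CD spectrum (two Gaussian troughs)
#'
#' Convenience constructor for a smooth far-UV spectrum with troughs of
#' chosen depth at 208 and 222 nm plus the positive band near 192 nm; used
#' in examples and as a building block for simulated spectra.
#'
#' @param wavelengths Grid in nm (default 190-260 by 1).
#' @param depth208,depth222 Trough depths (negative MRE, arbitrary units).
#' @param pos192 Positive band amplitude at 192 nm.
#' @return A spectrum tibble (`wavelength`, `ellipticity`).
#' @export
synthetic_helix_spectrum <- function(wavelengths = 190:260,
                                     depth208 = -10, depth222 = -9.6,
                                     pos192 = 18) {
  g <- function(center, width) exp(-((wavelengths - center) / width)^2)
  tibble(wavelength = as.numeric(wavelengths),
         ellipticity = pos192 * g(192, 4.5) + depth208 * g(208, 5.5) +
           depth222 * g(222, 6.5))
}

#' Reference basis set for CD deconvolution
#'
#' A synthetic, unit-tested basis of five secondary-structure classes
#' (`regular_helix`, `distorted_helix`, `right_twist`, `turn`, `other`)
#' built from smooth Gaussian bands with the canonical band positions of
#' each class. It is a documented stand-in for server-derived reference
#' sets (which are not redistributable); [deconvolve_cd()] accepts any
#' user-supplied basis on a common grid in the same layout.
#'
#' @param wavelengths Grid in nm (default 190-260 by 1).
#' @return A tibble with column `wavelength` plus one column per class.
#' @export
cd_basis_default <- function(wavelengths = 190:260) {
  wl <- as.numeric(wavelengths)
  g <- function(center, width) exp(-((wl - center) / width)^2)
  tibble(
    wavelength = wl,
    regular_helix  = 65 * g(192, 4.5) - 38 * g(208, 5.5) - 37 * g(222, 6.5),
    distorted_helix = 35 * g(190, 5) - 24 * g(206, 6) - 12 * g(222, 8),
    right_twist    = 30 * g(196, 5) - 20 * g(217, 7),
    turn           = 12 * g(205, 6) - 5 * g(225, 8),
    other          = -18 * g(198, 7) + 4 * g(218, 10)
  )
}

#' Deconvolve a CD spectrum into secondary-structure fractions
#'
#' Fits the spectrum as a non-negative linear combination of reference
#' basis spectra (non-negative least squares) and normalizes the
#' coefficients to fractions summing to 1. The spectrum and basis are
#' intersected on their common wavelength grid.
#'
#' @param spectrum A spectrum tibble (`wavelength`, `ellipticity`).
#' @param basis A basis tibble: `wavelength` plus one column per class
#'   (default [cd_basis_default()]).
#' @return A list of class `cd_deconvolution`: `fractions` (named, sums to
#'   1), `coefficients` (raw non-negative), `residual_norm` (Euclidean norm
#'   of the fit residual), `rmsd`, `n_wavelengths`.
#' @examples
#' b <- cd_basis_default()
#' mix <- tibble::tibble(wavelength = b$wavelength,
#'                       ellipticity = 0.6 * b$regular_helix + 0.4 * b$other)
#' deconvolve_cd(mix, b)$fractions
#' @export
deconvolve_cd <- function(spectrum, basis = cd_basis_default()) {
  check_spectrum(spectrum)
  stopifnot(is.data.frame(basis), "wavelength" %in% names(basis))
  classes <- setdiff(names(basis), "wavelength")
  if (length(classes) < 2L) abort("basis needs at least two class columns")
  common <- intersect(spectrum$wavelength, basis$wavelength)
  if (length(common) < length(classes) + 1L) {
    abort("spectrum and basis share too few wavelengths for deconvolution")
  }
  y <- spectrum$ellipticity[match(common, spectrum$wavelength)]
  A <- as.matrix(basis[match(common, basis$wavelength), classes])
  if (qr(A)$rank < ncol(A)) {
    abort("degenerate basis: reference spectra are collinear")
  }
  fit <- pracma::lsqnonneg(A, y)
  coefs <- setNames(as.numeric(fit$x), classes)
  total <- sum(coefs)
  fractions <- if (total > 0) coefs / total else coefs
  resid <- y - as.numeric(A %*% fit$x)
  structure(list(fractions = fractions, coefficients = coefs,
                 residual_norm = sqrt(sum(resid^2)),
                 rmsd = sqrt(mean(resid^2)),
                 n_wavelengths = length(common)),
            class = "cd_deconvolution")
}

#' @export
print.cd_deconvolution <- function(x, ...) {
  cat("CD deconvolution (non-negative least squares)\n")
  fr <- sprintf("  %-16s %5.1f%%", names(x$fractions), 100 * x$fractions)
  cat(fr, sep = "\n")
  cat(sprintf("  residual norm %.4g over %d wavelengths\n",
              x$residual_norm, x$n_wavelengths))
  invisible(x)
}

#' Read a two-column CD spectrum
#'
#' @param path TSV/CSV with header columns `wavelength` (or
#'   `wavelength_nm`) and `ellipticity`; `#` comment lines ignored.
#' @return A spectrum tibble.
#' @export
read_cd_spectrum <- function(path) {
  d <- readr::read_delim(path, delim = guess_delim(path),
                         show_col_types = FALSE, comment = "#")
  names(d)[names(d) == "wavelength_nm"] <- "wavelength"
  check_spectrum(d[c("wavelength", "ellipticity")])
  as_tibble(d[c("wavelength", "ellipticity")])
}

guess_delim <- function(path) {
  first <- readLines(path, n = 10L)
  first <- first[!startsWith(first, "#")][1]
  if (grepl(",", first, fixed = TRUE)) "," else "\t"
}
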