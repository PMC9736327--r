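## Differential scanning calorimetry: baseline subtraction, Tm and
## calorimetric enthalpy extraction, optional two-state (van't Hoff) fit.

R_GAS_KJ <- 8.31446261815324e-3  # kJ mol^-1 K^-1

#' Two-state excess heat capacity model
#'
#' \deqn{C_p(T) = \Delta H^2 K / (R T^2 (1 + K)^2)}
#' with \eqn{K(T) = \exp[(\Delta H / R)(1/T_m - 1/T)]}, temperatures in
#' kelvin, \eqn{\Delta H} in kJ/mol and \eqn{\Delta C_p} between the folded
#' and unfolded states fixed at 0.
#'
#' @param temperature_c Temperatures in degrees C.
#' @param tm Midpoint temperature, degrees C.
#' @param dh Van't Hoff enthalpy, kJ/mol.
#' @return Excess heat capacity, kJ mol^-1 K^-1.
#' @export
two_state_cp <- function(temperature_c, tm, dh) {
  tk <- temperature_c + 273.15
  tmk <- tm + 273.15
  k <- exp((dh / R_GAS_KJ) * (1 / tmk - 1 / tk))
  dh^2 * k / (R_GAS_KJ * tk^2 * (1 + k)^2)
}

check_thermogram <- function(thermogram) {
  stopifnot(is.data.frame(thermogram),
            all(c("temperature", "cp") %in% names(thermogram)))
  t <- thermogram$temperature
  if (length(t) < 2L || any(diff(t) <= 0)) {
    abort("thermogram temperatures must be strictly increasing")
  }
  if (anyNA(thermogram$cp) || any(!is.finite(thermogram$cp))) {
    abort("thermogram cp values must be finite")
  }
  invisible(TRUE)
}

#' Subtract a linear chemical baseline from a thermogram
#'
#' Fits a straight line through the mean cp of a pre-transition and a
#' post-transition temperature window and subtracts it, so the corrected
#' trace is ~0 in both windows. (Instrument buffer-scan subtraction is
#' assumed done upstream.) A warning is issued when either window appears
#' to overlap the transition (window slope large compared with the
#' across-window trend).
#'
#' @param thermogram Tibble with columns `temperature` (degrees C, strictly
#'   increasing) and `cp`.
#' @param pre_window,post_window Length-2 numeric ranges (degrees C) inside
#'   the data, pre before post, flanking the transition.
#' @return The baseline-corrected thermogram tibble.
#' @export
subtract_baseline <- function(thermogram, pre_window, post_window) {
  check_thermogram(thermogram)
  stopifnot(length(pre_window) == 2L, length(post_window) == 2L)
  pre_window <- sort(pre_window)
  post_window <- sort(post_window)
  if (pre_window[2] >= post_window[1]) {
    abort("pre_window must lie entirely below post_window")
  }
  t <- thermogram$temperature
  if (pre_window[1] < min(t) || post_window[2] > max(t)) {
    abort("baseline windows must lie inside the temperature range")
  }
  in_pre <- t >= pre_window[1] & t <= pre_window[2]
  in_post <- t >= post_window[1] & t <= post_window[2]
  if (sum(in_pre) < 2L || sum(in_post) < 2L) {
    abort("each baseline window must contain at least 2 points")
  }
  m_pre <- c(mean(t[in_pre]), mean(thermogram$cp[in_pre]))
  m_post <- c(mean(t[in_post]), mean(thermogram$cp[in_post]))
  slope <- (m_post[2] - m_pre[2]) / (m_post[1] - m_pre[1])
  # transition-overlap heuristic: within-window slope much steeper than the
  # across-window trend suggests the window sits on the peak flank
  for (w in list(thermogram[in_pre, ], thermogram[in_post, ])) {
    ws <- coef(stats::lm(cp ~ temperature, data = w))[2]
    if (is.finite(ws) && abs(ws) > 5 * (abs(slope) + 1e-8) &&
        diff(range(w$cp)) > 0.05 * diff(range(thermogram$cp))) {
      warn("baseline window appears to overlap the transition")
    }
  }
  base <- m_pre[2] + slope * (t - m_pre[1])
  dplyr::mutate(thermogram, cp = .data$cp - base)
}

#' Analyze a baseline-corrected thermogram
#'
#' Extracts the unfolding midpoint `tm` (temperature of maximum cp, refined
#' by a parabola through the apex and its neighbours), the calorimetric
#' enthalpy `dh_cal` (trapezoidal integral of cp over the scan) and, when
#' `two_state = TRUE`, the van't Hoff enthalpy `dh_vh` from a two-state fit
#' of [two_state_cp()]. For a genuinely two-state transition
#' `dh_vh / dh_cal` is ~1 (a single cooperative unit).
#'
#' @param thermogram Baseline-corrected tibble (`temperature` degrees C,
#'   `cp` kJ mol^-1 K^-1), >= 50 points across the transition, one dominant
#'   endothermic peak.
#' @param two_state Logical: also fit the two-state model (default `TRUE`).
#' @param noise_k Peak-detection guard: the maximum cp must exceed
#'   `noise_k` times the edge-window noise SD (default 5).
#' @return An object of class `unfolding_fit` with fields `tm` (degrees C),
#'   `dh_cal`, `dh_vh` (kJ/mol, `NA` if not fitted), `fit_rmsd`,
#'   `n_points`; methods [tidy()], [glance()], `autoplot()`.
#' @examples
#' tg <- tibble::tibble(temperature = seq(30, 90, 0.2),
#'                      cp = two_state_cp(seq(30, 90, 0.2), tm = 60, dh = 300))
#' analyze_thermogram(tg)
#' @export
analyze_thermogram <- function(thermogram, two_state = TRUE, noise_k = 5) {
  check_thermogram(thermogram)
  t <- thermogram$temperature
  cp <- thermogram$cp
  n <- length(t)
  if (n < 50L) abort("thermogram needs at least 50 points for analysis")
  edge <- max(5L, n %/% 10L)
  noise <- sd(c(head(cp, edge), tail(cp, edge)))
  imax <- which.max(cp)
  if (cp[imax] <= noise_k * max(noise, 1e-12)) {
    abort("no detectable peak: maximum cp is below the noise floor")
  }
  # parabolic apex refinement
  if (imax > 1L && imax < n) {
    i3 <- (imax - 1L):(imax + 1L)
    pf <- coef(stats::lm(y ~ x + I(x^2),
                         data = data.frame(x = t[i3], y = cp[i3])))
    tm <- if (is.finite(pf[3]) && pf[3] < 0) {
      as.numeric(-pf[2] / (2 * pf[3]))
    } else t[imax]
  } else {
    tm <- t[imax]
  }
  dh_cal <- pracma::trapz(t, cp)
  dh_vh <- NA_real_
  rmsd <- NA_real_
  if (two_state) {
    fit <- tryCatch(
      minpack.lm::nlsLM(cp ~ two_state_cp(temperature, tm, dh),
                        data = thermogram,
                        start = list(tm = tm, dh = max(dh_cal, 10)),
                        lower = c(tm = min(t), dh = 1),
                        upper = c(tm = max(t), dh = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      dh_vh <- unname(coef(fit)["dh"])
      tm <- unname(coef(fit)["tm"])
      rmsd <- sqrt(mean(stats::residuals(fit)^2))
    } else {
      warn("two-state fit did not converge; reporting peak-based tm only")
    }
  }
  structure(list(tm = tm, dh_cal = dh_cal, dh_vh = dh_vh,
                 fit_rmsd = rmsd, n_points = n,
                 data = as_tibble(thermogram)),
            class = "unfolding_fit")
}

#' @export
print.unfolding_fit <- function(x, ...) {
  cat("DSC unfolding analysis\n")
  cat(sprintf("  Tm      %.2f degC\n", x$tm))
  cat(sprintf("  dH_cal  %.1f kJ/mol\n", x$dh_cal))
  if (!is.na(x$dh_vh)) {
    cat(sprintf("  dH_vH   %.1f kJ/mol (two-state fit, rmsd %.3g)\n",
                x$dh_vh, x$fit_rmsd))
  }
  invisible(x)
}

#' @rdname analyze_thermogram
#' @param x An `unfolding_fit`.
#' @param ... Unused.
#' @method tidy unfolding_fit
#' @export
tidy.unfolding_fit <- function(x, ...) {
  tibble(term = c("tm", "dh_cal", "dh_vh"),
         estimate = c(x$tm, x$dh_cal, x$dh_vh),
         unit = c("degC", "kJ/mol", "kJ/mol"))
}

#' @rdname analyze_thermogram
#' @method glance unfolding_fit
#' @export
glance.unfolding_fit <- function(x, ...) {
  tibble(tm = x$tm, dh_cal = x$dh_cal, dh_vh = x$dh_vh,
         cooperative_ratio = x$dh_vh / x$dh_cal, fit_rmsd = x$fit_rmsd,
         nobs = x$n_points)
}

#' Read a thermogram TSV
#'
#' @param path TSV with header columns `temperature_C` (or `temperature`)
#'   and `cp`; `#` comment lines ignored.
#' @return A thermogram tibble.
#' @export
read_thermogram <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  names(d)[names(d) == "temperature_C"] <- "temperature"
  check_thermogram(d[c("temperature", "cp")])
  as_tibble(d[c("temperature", "cp")])
}
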