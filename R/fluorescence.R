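## Steady-state fluorescence: G-factor, anisotropy, FRET efficiency and
## hyperbolic binding-titration fits.

#' Grating (G) factor from the 90-degree polarized pair
#'
#' `G = I(90/0) / I(90/90)` corrects the instrument's polarization bias.
#'
#' @param i_90_0,i_90_90 Intensities with the excitation polarizer at 90
#'   degrees and the emission polarizer at 0 / 90 degrees. Both must be
#'   strictly positive.
#' @return The dimensionless grating factor.
#' @export
g_factor <- function(i_90_0, i_90_90) {
  if (any(i_90_0 <= 0) || any(i_90_90 <= 0)) {
    abort("G-factor intensities must be strictly positive")
  }
  i_90_0 / i_90_90
}

#' Steady-state fluorescence anisotropy
#'
#' \deqn{r = (I_\parallel - G I_\perp) / (I_\parallel + 2 G I_\perp)}
#' where the parallel and perpendicular intensities are measured with
#' polarizers at 0/0 and 0/90 degrees. Supply either `g` directly or the
#' 90-degree pair (`i_90_0`, `i_90_90`) from which it is computed.
#'
#' Vectorized over intensities; with `g = 1` and non-negative intensities
#' the result lies in \[-0.5, 1\].
#'
#' @param i_par,i_perp Parallel / perpendicular intensities (>= 0).
#' @param g Grating factor (default 1); ignored if the 90-degree pair is
#'   given.
#' @param i_90_0,i_90_90 Optional intensities for [g_factor()].
#' @return Anisotropy values, dimensionless.
#' @examples
#' anisotropy(2, 1)           # 0.25
#' anisotropy(2, 1, g = 1.2)  # G-corrected
#' @export
anisotropy <- function(i_par, i_perp, g = 1,
                       i_90_0 = NULL, i_90_90 = NULL) {
  if (!is.null(i_90_0) && !is.null(i_90_90)) {
    g <- g_factor(i_90_0, i_90_90)
  }
  if (any(g <= 0)) abort("grating factor must be positive")
  if (any(i_par < 0) || any(i_perp < 0)) {
    abort("polarized intensities must be non-negative")
  }
  denom <- i_par + 2 * g * i_perp
  if (any(denom <= 0)) abort("total polarized intensity must be positive")
  (i_par - g * i_perp) / denom
}

#' Polarized intensity pair realizing a target anisotropy
#'
#' Inverse of [anisotropy()]: given a target `r`, total intensity
#' `S = i_par + 2 g i_perp` and grating factor, returns the consistent
#' polarized intensities (and a 90-degree pair realizing `g`). Useful for
#' constructing measurement-shaped inputs with known ground truth.
#'
#' @param r Target anisotropy in (-0.5, 1\].
#' @param total Total intensity `S` (default 100, arbitrary units).
#' @param g Grating factor (default 1).
#' @param i_90_90 Intensity assigned to the 90/90 channel (default 50).
#' @return A one-row tibble: `i_par`, `i_perp`, `i_90_0`, `i_90_90`, `g`,
#'   `r`.
#' @export
polarized_from_anisotropy <- function(r, total = 100, g = 1, i_90_90 = 50) {
  if (any(r <= -0.5) || any(r > 1)) abort("anisotropy must lie in (-0.5, 1]")
  if (any(total <= 0) || any(g <= 0)) {
    abort("total intensity and grating factor must be positive")
  }
  tibble(i_par = total * (1 + 2 * r) / 3,
         i_perp = total * (1 - r) / (3 * g),
         i_90_0 = g * i_90_90, i_90_90 = i_90_90, g = g, r = r)
}

#' FRET efficiency from donor quenching
#'
#' `E = 1 - F_DA / F_D`, the fractional quenching of the donor fluorescence
#' by the acceptor. Apparent donor enhancement (`f_da > f_d`) is reported
#' as efficiency 0 with a warning rather than an error, so pipelines keep
#' running on noisy data.
#'
#' @param f_da Donor fluorescence in the presence of the acceptor.
#' @param f_d Donor-only fluorescence (> 0).
#' @return Efficiency in \[0, 1\].
#' @examples
#' fret_efficiency(84, 100)  # 0.16
#' @export
fret_efficiency <- function(f_da, f_d) {
  if (any(f_d <= 0)) abort("donor-only fluorescence must be positive")
  if (any(f_da < 0)) abort("donor fluorescence must be non-negative")
  e <- 1 - f_da / f_d
  if (any(e < 0)) {
    warn("donor enhancement (f_da > f_d): efficiency reported as 0")
    e[e < 0] <- 0
  }
  e
}

#' Fit a hyperbolic binding titration
#'
#' Fits the single-site saturation model
#' \deqn{y(x) = baseline \pm P_1 \, x / (K_d + x)}
#' to a titration (sign `+` for increasing observables such as FRET-fed
#' fluorescence, `-` for decreasing ones such as anisotropy), by bounded
#' Levenberg-Marquardt least squares with `P1 >= 0`, `Kd > 0`.
#' Initialization comes from the data (baseline = y at the lowest x; P1 =
#' |y_last - y_first|; Kd = x at half amplitude by interpolation); up to
#' three seeded random restarts are attempted on non-convergence.
#'
#' A series with no resolvable amplitude (flat within numerical noise) is
#' returned with `amplitude_zero = TRUE`, `p1 = 0` and `kd = NA` rather
#' than an error.
#'
#' @param series A tibble with columns `x` (titrant concentration, uM,
#'   strictly increasing, including x = 0 for a measured baseline) and `y`
#'   (observable). At least 5 points.
#' @param kind `"increase"` or `"decrease"`; the sign of the saturation
#'   term.
#' @param fix_baseline Logical (default `FALSE`): pin the baseline to the
#'   observation at the lowest x instead of fitting it.
#' @return An object of class `binding_fit`: access parameters with
#'   [tidy()], fit statistics with [glance()], fitted curves with
#'   `predict()`, and a data-plus-fit plot with `autoplot()`. Fields
#'   include `p1`, `kd`, `baseline`, `plateau`
#'   (`baseline + p1` for increasing, `baseline - p1` for decreasing),
#'   standard errors, `r_squared` and `amplitude_zero`.
#' @examples
#' ti <- simulate_scenario("anisotropy_titration", seed = 1)
#' fit <- fit_hyperbolic(ti$data, kind = "decrease")
#' glance(fit)
#' @export
fit_hyperbolic <- function(series, kind = c("increase", "decrease"),
                           fix_baseline = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(series), all(c("x", "y") %in% names(series)))
  x <- as.numeric(series$x)
  y <- as.numeric(series$y)
  if (length(x) < 5L) abort("titration needs at least 5 points")
  if (any(diff(x) <= 0)) abort("titrant concentrations must be strictly increasing")
  if (any(x < 0) || anyNA(y) || any(!is.finite(y))) {
    abort("concentrations must be non-negative and observables finite")
  }
  sgn <- if (kind == "increase") 1 else -1
  b0 <- y[1]
  amp0 <- abs(y[length(y)] - y[1])
  scale_y <- max(abs(y), 1e-12)
  if (diff(range(y)) <= 1e-10 * scale_y) {
    return(new_binding_fit(kind, p1 = 0, kd = NA_real_, baseline = b0,
                           se = c(p1 = NA_real_, kd = NA_real_,
                                  baseline = NA_real_),
                           r_squared = NA_real_, x = x, y = y,
                           fix_baseline = fix_baseline,
                           amplitude_zero = TRUE))
  }
  # Kd guess: x at half-amplitude by interpolation of the monotone trend
  yr <- sgn * (y - b0)
  half <- amp0 / 2
  kd0 <- tryCatch({
    ap <- approx(cummax(pmax(yr, 0)), x, xout = half, ties = "ordered")$y
    if (is.na(ap) || ap <= 0) max(x) / 4 else ap
  }, error = function(e) max(x) / 4)
  fitfun <- function(start) {
    if (fix_baseline) {
      minpack.lm::nlsLM(
        y ~ b0 + s * p1 * x / (kd + x),
        data = data.frame(x = x, y = y, s = sgn, b0 = b0),
        start = start[c("p1", "kd")],
        lower = c(p1 = 0, kd = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(
        y ~ baseline + s * p1 * x / (kd + x),
        data = data.frame(x = x, y = y, s = sgn),
        start = start,
        lower = c(p1 = 0, kd = 1e-9, baseline = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }
  start <- list(p1 = max(amp0, 1e-8 * scale_y), kd = kd0, baseline = b0)
  fit <- tryCatch(fitfun(start), error = function(e) e)
  if (inherits(fit, "error")) {
    for (i in 1:3) {  # seeded restarts on non-convergence
      jit <- withr_seed(1000 + i, function() runif(2, 0.25, 4))
      st <- list(p1 = start$p1 * jit[1], kd = start$kd * jit[2],
                 baseline = b0)
      fit <- tryCatch(fitfun(st), error = function(e) e)
      if (!inherits(fit, "error")) break
    }
  }
  if (inherits(fit, "error")) {
    abort(paste0("hyperbolic fit did not converge: ",
                 conditionMessage(fit)))
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  baseline <- if (fix_baseline) b0 else unname(cf["baseline"])
  se_full <- c(p1 = unname(se["p1"]), kd = unname(se["kd"]),
               baseline = if (fix_baseline) NA_real_ else
                 unname(se["baseline"]))
  yhat <- baseline + sgn * cf["p1"] * x / (cf["kd"] + x)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  new_binding_fit(kind, p1 = unname(cf["p1"]), kd = unname(cf["kd"]),
                  baseline = baseline, se = se_full,
                  r_squared = 1 - ss_res / ss_tot, x = x, y = y,
                  fix_baseline = fix_baseline, amplitude_zero = FALSE)
}

withr_seed <- function(seed, f) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  f()
}

new_binding_fit <- function(kind, p1, kd, baseline, se, r_squared, x, y,
                            fix_baseline, amplitude_zero) {
  plateau <- if (amplitude_zero) baseline else {
    baseline + (if (kind == "increase") p1 else -p1)
  }
  structure(list(kind = kind, p1 = p1, kd = kd, baseline = baseline,
                 plateau = plateau, se = se, r_squared = r_squared,
                 n_points = length(x), data = tibble(x = x, y = y),
                 fix_baseline = fix_baseline,
                 amplitude_zero = amplitude_zero),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Hyperbolic binding fit (%s), %d points\n", x$kind,
              x$n_points))
  if (x$amplitude_zero) {
    cat("  amplitude indistinguishable from zero; Kd not estimable\n")
  } else {
    cat(sprintf("  Kd       %.4g +/- %.2g uM\n", x$kd, x$se["kd"]))
    cat(sprintf("  P1       %.4g +/- %.2g\n", x$p1, x$se["p1"]))
    cat(sprintf("  baseline %.4g%s   plateau %.4g\n", x$baseline,
                if (x$fix_baseline) " (fixed)" else "", x$plateau))
    cat(sprintf("  R^2      %.4f\n", x$r_squared))
  }
  invisible(x)
}

#' @rdname fit_hyperbolic
#' @param object,x A `binding_fit`.
#' @param newdata Optional tibble with column `x` for `predict()`.
#' @param ... Unused.
#' @method predict binding_fit
#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  xv <- if (is.null(newdata)) object$data$x else newdata$x
  if (object$amplitude_zero) return(rep(object$baseline, length(xv)))
  sgn <- if (object$kind == "increase") 1 else -1
  object$baseline + sgn * object$p1 * xv / (object$kd + xv)
}

#' @rdname fit_hyperbolic
#' @method tidy binding_fit
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble(term = c("p1", "kd", "baseline"),
         estimate = c(x$p1, x$kd, x$baseline),
         std.error = unname(x$se[c("p1", "kd", "baseline")]))
}

#' @rdname fit_hyperbolic
#' @method glance binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(kd = x$kd, p1 = x$p1, baseline = x$baseline, plateau = x$plateau,
         r.squared = x$r_squared, nobs = x$n_points,
         amplitude_zero = x$amplitude_zero)
}

#' Fit the donor-quenching dependence on acceptor concentration
#'
#' Converts a donor-fluorescence series measured at increasing acceptor
#' (e.g. DPH) concentrations into fractional quenching
#' `q(x) = 1 - F(x)/F(0)` and fits `q = P1 x / (Kd + x)` through the
#' origin. Use [quenching_at()] to evaluate the fitted percent quenching at
#' any acceptor concentration.
#'
#' @param series Tibble with columns `x` (acceptor concentration, uM,
#'   including 0) and `f` (donor fluorescence, > 0 at x = 0).
#' @return A `binding_fit` (subclass `quenching_fit`) on the fractional
#'   quenching scale.
#' @examples
#' g <- simulate_scenario("dph_quenching", seed = 1)
#' qf <- quenching_curve(g$data)
#' quenching_at(qf, 2)   # percent quenching at 2 uM acceptor
#' @export
quenching_curve <- function(series) {
  stopifnot(is.data.frame(series), all(c("x", "f") %in% names(series)))
  x <- as.numeric(series$x)
  f <- as.numeric(series$f)
  if (x[1] != 0) abort("quenching series must include x = 0 (donor-only)")
  if (f[1] <= 0) abort("donor-only fluorescence must be positive")
  q <- 1 - f / f[1]
  fit <- fit_hyperbolic(tibble(x = x, y = q), kind = "increase",
                        fix_baseline = TRUE)
  class(fit) <- c("quenching_fit", class(fit))
  fit
}

#' Evaluate a fitted quenching curve
#'
#' @param fit A `quenching_fit` from [quenching_curve()].
#' @param at Acceptor concentration(s), uM.
#' @return Percent quenching (0-100 scale) at `at`.
#' @export
quenching_at <- function(fit, at) {
  stopifnot(inherits(fit, "quenching_fit"))
  100 * predict(fit, newdata = tibble(x = at))
}
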