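## Seeded synthetic-data generators. Every scenario emits both a data
## artifact in the format its analysis stage reads and a ground-truth record
## sufficient to score that stage. Identical (scenario, seed, overrides)
## produce identical output.
##
## Scenario defaults encode the study conditions of the caveolin-2 /
## cholesterol membrane-interaction experiments this package models:
## half-maximal concentrations 0.75 uM (FRET-fed DPH fluorescence increase)
## and 0.48 uM (DPH anisotropy decrease in 30%-cholesterol vesicles),
## anisotropy baseline 0.21 falling to plateau 0.17 (0.12 flat without /
## with 5% cholesterol), 16% FRET efficiency at saturation, ~60% donor
## quenching at 2 uM DPH, and DSC stabilization ordering
## buffer < +SUV < +SUV+cholesterol. Amplitudes with no reported value
## (instrument arbitrary units, G factor, DSC Tm/dH magnitudes) are round
## artifact choices, documented in scenario_defaults().

#' Documented defaults for every generator scenario
#'
#' Returns the full default parameter map of one scenario (or all of them),
#' the single authoritative constants table behind
#' [simulate_scenario()].
#'
#' @param scenario Optional scenario name; omit for the full list.
#' @return A named list of default parameters (or a list of such lists).
#' @export
scenario_defaults <- function(scenario = NULL) {
  defaults <- list(
    fret_titration = list(
      kd = 0.75,            # uM, half-maximal fluorescence increase
      baseline = 100,       # a.u. [artifact choice]
      p1 = 50,              # a.u. amplitude [artifact choice]
      n_points = 8L, x_max = 3, noise_sd = 0),
    anisotropy_titration = list(
      condition = "chol30",
      kd = 0.48,            # uM, half-maximal anisotropy decrease
      baseline = 0.21,      # r of DPH in 30% cholesterol vesicles
      amplitude = 0.04,     # 0.21 -> 0.17 plateau
      flat_r = 0.12,        # r for the 0% / 5% cholesterol conditions
      n_points = 8L, x_max = 3, noise_sd = 0),
    dph_quenching = list(
      f0 = 100,             # donor-only fluorescence, a.u. [artifact choice]
      p1 = 0.9,             # saturating quenching fraction [artifact choice]
      kd = 1.0,             # uM; gives 60% fitted quenching at 2 uM
      n_points = 9L, x_max = 8, noise_sd = 0),
    fret_saturation = list(
      f_d = 100,            # a.u. [artifact choice]
      efficiency = 0.16),   # saturating FRET efficiency
    polarized_baseline = list(
      condition = "chol30",
      r_chol30 = 0.21, r_flat = 0.12,
      total = 100,          # a.u. [artifact choice]
      g = 1.1,              # grating factor [artifact choice]
      i_90_90 = 50),        # a.u. [artifact choice]
    dsc_three_condition = list(
      tm = c(buffer = 55, suv = 60, suv_chol = 64),       # degC [artifact]
      dh = c(buffer = 200, suv = 300, suv_chol = 360),    # kJ/mol [artifact]
      t_min = 30, t_max = 90, t_step = 0.2, noise_sd = 0),
    motif_plant = list(
      length = 160L, motif = "carc", start = 81L,
      gap1 = 3L, gap2 = 2L),
    cd_mixture = list(
      fractions = c(regular_helix = 0.6, distorted_helix = 0.4,
                    right_twist = 0, turn = 0, other = 0),
      noise_sd = 0),        # relative to the max |ellipticity|
    disorder_profile = list(
      n = 162L, fraction = 0.46, threshold = 0.5)
  )
  if (is.null(scenario)) return(defaults)
  if (!scenario %in% names(defaults)) {
    abort(paste0("unknown scenario '", scenario, "'; known: ",
                 paste(names(defaults), collapse = ", ")))
  }
  defaults[[scenario]]
}

#' Generate a synthetic dataset with known ground truth
#'
#' Produces, for one named scenario, the data artifact its analysis stage
#' consumes plus a ground-truth record sufficient to score that stage.
#' Output is a deterministic function of `(scenario, seed, overrides)`.
#'
#' Scenarios: `fret_titration`, `anisotropy_titration`, `dph_quenching`,
#' `fret_saturation`, `polarized_baseline`, `dsc_three_condition`,
#' `motif_plant`, `cd_mixture`, `disorder_profile`. See
#' [scenario_defaults()] for every parameter and its default.
#'
#' @param scenario Scenario name.
#' @param seed Integer RNG seed (default 1).
#' @param overrides Named list overriding documented defaults; unknown
#'   names are an error.
#' @return A list with elements `scenario`, `seed`, `params` (defaults
#'   merged with overrides), `data` (tibble, or sequence table for
#'   `motif_plant`) and `truth` (named list).
#' @examples
#' g <- simulate_scenario("anisotropy_titration", seed = 7)
#' g$truth$kd
#' @export
simulate_scenario <- function(scenario, seed = 1L, overrides = list()) {
  p <- scenario_defaults(scenario)
  if (length(overrides) > 0L) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad) > 0L || is.null(names(overrides))) {
      abort(paste0("unknown override(s) for scenario '", scenario, "': ",
                   paste(bad, collapse = ", ")))
    }
    p[names(overrides)] <- overrides
  }
  gen <- switch(scenario,
    fret_titration = gen_titration(p, kind = "increase"),
    anisotropy_titration = gen_anisotropy(p),
    dph_quenching = gen_quenching(p),
    fret_saturation = gen_fret_saturation(p),
    polarized_baseline = gen_polarized(p),
    dsc_three_condition = gen_dsc(p),
    motif_plant = gen_motif(p),
    cd_mixture = gen_cd(p),
    disorder_profile = gen_disorder(p)
  )
  out <- withr_seed(as.integer(seed), gen)
  c(list(scenario = scenario, seed = as.integer(seed), params = p), out)
}

gen_titration <- function(p, kind) {
  function() {
    x <- seq(0, p$x_max, length.out = p$n_points)
    sgn <- if (kind == "increase") 1 else -1
    y <- p$baseline + sgn * p$p1 * x / (p$kd + x)
    if (p$noise_sd > 0) y <- y + rnorm(length(y), 0, p$noise_sd * p$p1)
    list(data = tibble(x = x, y = y,
                       observable_kind = "fluorescence_increase"),
         truth = list(kd = p$kd, p1 = p$p1, baseline = p$baseline,
                      plateau = p$baseline + sgn * p$p1, kind = kind))
  }
}

gen_anisotropy <- function(p) {
  function() {
    x <- seq(0, p$x_max, length.out = p$n_points)
    if (p$condition == "chol30") {
      y <- p$baseline - p$amplitude * x / (p$kd + x)
      truth <- list(kd = p$kd, p1 = p$amplitude, baseline = p$baseline,
                    plateau = p$baseline - p$amplitude, kind = "decrease",
                    condition = p$condition)
    } else {
      y <- rep(p$flat_r, length(x))
      truth <- list(kd = NA_real_, p1 = 0, baseline = p$flat_r,
                    plateau = p$flat_r, kind = "flat",
                    condition = p$condition)
    }
    if (p$noise_sd > 0) {
      y <- y + rnorm(length(y), 0, p$noise_sd * max(p$amplitude, 1e-12))
    }
    list(data = tibble(x = x, y = y,
                       observable_kind = "anisotropy_decrease",
                       condition = p$condition),
         truth = truth)
  }
}

gen_quenching <- function(p) {
  function() {
    x <- seq(0, p$x_max, length.out = p$n_points)
    q <- p$p1 * x / (p$kd + x)
    f <- p$f0 * (1 - q)
    if (p$noise_sd > 0) f <- f + rnorm(length(f), 0, p$noise_sd * p$f0)
    list(data = tibble(x = x, f = f),
         truth = list(kd = p$kd, p1 = p$p1, f0 = p$f0,
                      quenching_at_2uM = 100 * p$p1 * 2 / (p$kd + 2)))
  }
}

gen_fret_saturation <- function(p) {
  function() {
    f_da <- p$f_d * (1 - p$efficiency)
    list(data = tibble(f_d = p$f_d, f_da = f_da),
         truth = list(efficiency = p$efficiency,
                      efficiency_percent = 100 * p$efficiency))
  }
}

gen_polarized <- function(p) {
  function() {
    r <- if (p$condition == "chol30") p$r_chol30 else p$r_flat
    pol <- polarized_from_anisotropy(r, total = p$total, g = p$g,
                                     i_90_90 = p$i_90_90)
    pol$condition <- p$condition
    list(data = pol, truth = list(r = r, g = p$g, condition = p$condition))
  }
}

gen_dsc <- function(p) {
  function() {
    temps <- seq(p$t_min, p$t_max, by = p$t_step)
    conds <- names(p$tm)
    data <- purrr::map_dfr(conds, function(cn) {
      cp <- two_state_cp(temps, p$tm[[cn]], p$dh[[cn]])
      if (p$noise_sd > 0) cp <- cp + rnorm(length(cp), 0,
                                           p$noise_sd * max(cp))
      tibble(condition = cn, temperature = temps, cp = cp)
    })
    list(data = data,
         truth = list(tm = as.list(p$tm), dh = as.list(p$dh)))
  }
}

gen_motif <- function(p) {
  function() {
    pat <- motif_pattern(p$motif)
    anchor_letters <- unique(unlist(purrr::map(
      c("carc", "crac", "cbm"), ~ unlist(motif_pattern(.x)$sets))))
    background <- setdiff(AA20, anchor_letters)
    n <- p$length
    chars <- sample(background, n, replace = TRUE)
    a1 <- pat$sets[[1]][1]
    a2 <- pat$sets[[2]][1]
    a3 <- pat$sets[[3]][1]
    g1 <- min(max(p$gap1, pat$gaps[[1]][1]), pat$gaps[[1]][2])
    g2 <- min(max(p$gap2, pat$gaps[[2]][1]), pat$gaps[[2]][2])
    i <- p$start
    j <- i + g1 + 1L
    k <- j + g2 + 1L
    if (k > n) abort("planted motif does not fit in the sequence")
    chars[i] <- a1
    chars[j] <- a2
    chars[k] <- a3
    seqs <- protein_table("planted_1", paste(chars, collapse = ""))
    list(data = seqs,
         truth = list(motif = p$motif, start = i, end = k,
                      anchors = c(i, j, k)))
  }
}

gen_cd <- function(p) {
  function() {
    basis <- cd_basis_default()
    classes <- setdiff(names(basis), "wavelength")
    fr <- p$fractions
    if (!all(names(fr) %in% classes) || any(fr < 0)) {
      abort("cd_mixture fractions must be non-negative and named by basis class")
    }
    fr <- fr / sum(fr)
    w <- setNames(numeric(length(classes)), classes)
    w[names(fr)] <- fr
    y <- as.numeric(as.matrix(basis[classes]) %*% w)
    if (p$noise_sd > 0) y <- y + rnorm(length(y), 0, p$noise_sd * max(abs(y)))
    list(data = tibble(wavelength = basis$wavelength, ellipticity = y),
         truth = list(fractions = as.list(fr)))
  }
}

gen_disorder <- function(p) {
  function() {
    n <- p$n
    k <- round(p$fraction * n)
    thr <- p$threshold
    hi <- thr + (1 - thr) * rbeta(k, 2, 8)       # disordered block, N-terminal
    lo <- thr * rbeta(n - k, 2, 5) * 0.98        # strictly below threshold
    scores <- c(hi, lo)
    list(data = tibble(residue_index = seq_len(n), score = scores,
                       source = "synthetic"),
         truth = list(fraction = k / n, threshold = thr,
                      disordered_region = c(1L, k)))
  }
}

#' Write a generated scenario to disk in stage input formats
#'
#' Serializes the `data` part of a [simulate_scenario()] result in the
#' on-disk format the matching analysis stage reads (FASTA for sequences,
#' TSV with `#` metadata headers otherwise) plus the ground truth as
#' `truth.json`.
#'
#' @param gen A [simulate_scenario()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scenario <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  sc <- gen$scenario
  tsv <- function(d, name, meta = character()) {
    path <- file.path(dir, name)
    writeLines(c(meta, paste(names(d), collapse = "\t"),
                 do.call(paste, c(unname(as.list(d)), sep = "\t"))),
               path)
    path
  }
  if (sc == "motif_plant") {
    path <- file.path(dir, "sequences.fasta")
    writeLines(paste0(">", gen$data$id, "\n", gen$data$residues), path)
    paths <- c(paths, path)
  } else if (sc == "dsc_three_condition") {
    for (cn in unique(gen$data$condition)) {
      d <- gen$data[gen$data$condition == cn, c("temperature", "cp")]
      names(d) <- c("temperature_C", "cp")
      paths <- c(paths, tsv(d, paste0("dsc_", cn, ".tsv"),
                            paste0("# condition: ", cn)))
    }
  } else if (sc %in% c("fret_titration", "anisotropy_titration")) {
    d <- gen$data[c("x", "y")]
    names(d) <- c("x_uM", "y")
    meta <- paste0("# observable_kind: ", gen$data$observable_kind[1])
    if ("condition" %in% names(gen$data)) {
      meta <- c(meta, paste0("# condition: ", gen$data$condition[1]))
    }
    paths <- c(paths, tsv(d, "titration.tsv", meta))
  } else if (sc == "dph_quenching") {
    d <- gen$data
    names(d) <- c("x_uM", "f")
    paths <- c(paths, tsv(d, "quenching.tsv"))
  } else if (sc == "cd_mixture") {
    paths <- c(paths, tsv(gen$data, "spectrum.tsv"))
  } else if (sc == "disorder_profile") {
    paths <- c(paths, tsv(gen$data[c("residue_index", "score")],
                          "disorder.tsv"))
  } else if (sc == "polarized_baseline") {
    paths <- c(paths, tsv(gen$data, "polarized.tsv"))
  } else if (sc == "fret_saturation") {
    paths <- c(paths, tsv(gen$data, "fret_saturation.tsv"))
  }
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(c(list(scenario = sc, seed = gen$seed), gen$truth),
                       truth_path, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, truth_path)
  invisible(paths)
}
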