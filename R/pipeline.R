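## End-to-end orchestration: run enabled stages over on-disk inputs and
## produce a machine-readable report bundle.

#' Read a titration TSV
#'
#' Reads the two-column titration format (`x_uM`, `y` — or `f` for donor
#' fluorescence) with optional `#`-prefixed metadata lines
#' (`# observable_kind: ...`, `# condition: ...`).
#'
#' @param path TSV path.
#' @return A tibble with columns `x` plus `y` or `f`, carrying attributes
#'   `observable_kind` and `condition` when present in the header.
#' @export
read_titration <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  names(d)[names(d) == "x_uM"] <- "x"
  grab <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  attr(d, "observable_kind") <- grab("observable_kind")
  attr(d, "condition") <- grab("condition")
  as_tibble(d)
}

#' Read a polarized-intensity TSV
#'
#' Columns `i_par`, `i_perp` and optionally `i_90_0`, `i_90_90` (plus any
#' others, kept as-is); `#` comment lines ignored.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_polarized <- function(path) {
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("i_par", "i_perp") %in% names(d))) {
    abort("polarized TSV needs columns 'i_par' and 'i_perp'")
  }
  as_tibble(d)
}

#' Run the full analysis pipeline over on-disk inputs
#'
#' Executes the enabled stages in order over the supplied inputs and
#' returns a report bundle (one tibble or fit object per stage plus a
#' one-row-per-stage summary). All input paths are validated before any
#' stage runs; if any stage errors, the remaining stages still run and a
#' single error naming every failed stage is raised at the end.
#'
#' @param config A named list:
#'   \describe{
#'     \item{fasta}{FASTA path; enables the `motifs` and `hydropathy`
#'       stages.}
#'     \item{disorder}{disorder-profile TSV; enables `disorder`.}
#'     \item{cd_spectrum}{CD spectrum TSV/CSV; enables `cd` (ratio, shape,
#'       deconvolution). Optional `cd_basis` TSV overrides the built-in
#'       basis.}
#'     \item{titration}{titration TSV; enables `binding`
#'       (`titration_kind` `"increase"`/`"decrease"`, default from the
#'       file's `observable_kind` metadata, else `"increase"`).}
#'     \item{quenching}{donor-fluorescence-vs-acceptor TSV; enables
#'       `quenching`.}
#'     \item{polarized}{polarized-intensity TSV; enables `anisotropy`.}
#'     \item{dsc}{character vector of thermogram TSVs; enables `dsc`.}
#'     \item{stages}{optional character vector restricting which enabled
#'       stages run.}
#'     \item{out_dir}{optional directory; when given, per-stage TSV (or
#'       JSON) reports and a `summary` file are written.}
#'     \item{format}{`"tsv"` (default) or `"json"` for written reports.}
#'     \item{window_length, threshold}{hydropathy options (defaults 19, 0).}
#'   }
#' @return A list of class `memphys_report`: per-stage results plus
#'   `summary` (tibble: stage, status, detail).
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  stage_inputs <- list(
    motifs = "fasta", hydropathy = "fasta", disorder = "disorder",
    cd = "cd_spectrum", binding = "titration", quenching = "quenching",
    anisotropy = "polarized", dsc = "dsc")
  enabled <- names(stage_inputs)[purrr::map_lgl(
    stage_inputs, ~ !is.null(config[[.x]]))]
  if (!is.null(config$stages)) {
    unknown <- setdiff(config$stages, names(stage_inputs))
    if (length(unknown) > 0L) {
      abort(paste0("unknown stage(s): ", paste(unknown, collapse = ", ")))
    }
    enabled <- intersect(enabled, config$stages)
  }
  if (length(enabled) == 0L) {
    abort("no stages enabled: supply at least one input path")
  }
  for (st in enabled) {  # validate every path before any stage runs
    for (path in config[[stage_inputs[[st]]]]) {
      if (!file.exists(path)) {
        abort(paste0("stage '", st, "': input not found: ", path))
      }
    }
  }
  results <- list()
  status <- tibble(stage = character(), status = character(),
                   detail = character())
  run_stage <- function(name, f) {
    res <- tryCatch(f(), error = function(e) e)
    if (inherits(res, "error")) {
      status <<- dplyr::add_row(status, stage = name, status = "error",
                                detail = conditionMessage(res))
    } else {
      results[[name]] <<- res$value
      status <<- dplyr::add_row(status, stage = name, status = "ok",
                                detail = res$detail)
    }
  }
  if ("motifs" %in% enabled) run_stage("motifs", function() {
    seqs <- read_fasta(config$fasta)
    hits <- scan_motifs(seqs)
    list(value = hits, detail = paste0(nrow(hits), " motif hit(s)"))
  })
  if ("hydropathy" %in% enabled) run_stage("hydropathy", function() {
    seqs <- read_fasta(config$fasta)
    w <- config$window_length %||% 19L
    thr <- config$threshold %||% 0
    prof <- hydropathy_profile(seqs, window_length = w)
    segs <- call_segments(prof, threshold = thr)
    list(value = list(profile = prof, segments = segs),
         detail = paste0(nrow(segs), " favorable segment(s); window ", w,
                         ", threshold ", thr, " kcal/mol"))
  })
  if ("disorder" %in% enabled) run_stage("disorder", function() {
    prof <- read_disorder_profile(config$disorder)
    s <- fraction_disordered(prof, threshold = config$threshold %||% 0.5)
    list(value = s, detail = sprintf("fraction disordered %.3f", s$fraction))
  })
  if ("cd" %in% enabled) run_stage("cd", function() {
    spec <- read_cd_spectrum(config$cd_spectrum)
    ratio <- helix_ratio(spec)
    shape <- classify_shape(spec)
    basis <- if (!is.null(config$cd_basis)) {
      readr::read_tsv(config$cd_basis, show_col_types = FALSE, comment = "#")
    } else cd_basis_default()
    dec <- deconvolve_cd(spec, basis)
    list(value = list(ratio = ratio, shape = shape, deconvolution = dec),
         detail = sprintf("ratio %.3f (%s), %s", ratio$ratio,
                          ratio$classification, shape$shape))
  })
  if ("binding" %in% enabled) run_stage("binding", function() {
    ser <- read_titration(config$titration)
    kind <- config$titration_kind %||%
      switch(attr(ser, "observable_kind") %||% "fluorescence_increase",
             anisotropy_decrease = "decrease", donor_quenching = "decrease",
             "increase")
    fit <- fit_hyperbolic(ser, kind = kind,
                          fix_baseline = isTRUE(config$fix_baseline))
    list(value = fit,
         detail = sprintf("Kd %.4g µM (R² %.3f)", fit$kd, fit$r_squared))
  })
  if ("quenching" %in% enabled) run_stage("quenching", function() {
    ser <- read_titration(config$quenching)
    fit <- quenching_curve(ser)
    list(value = fit,
         detail = sprintf("Kd %.4g µM; %.1f%% quenching at 2 µM",
                          fit$kd, quenching_at(fit, 2)))
  })
  if ("anisotropy" %in% enabled) run_stage("anisotropy", function() {
    d <- read_polarized(config$polarized)
    r <- if (all(c("i_90_0", "i_90_90") %in% names(d))) {
      anisotropy(d$i_par, d$i_perp, i_90_0 = d$i_90_0, i_90_90 = d$i_90_90)
    } else {
      anisotropy(d$i_par, d$i_perp)
    }
    list(value = dplyr::mutate(d, r = r),
         detail = sprintf("r = %s", paste(sprintf("%.4g", r),
                                          collapse = ", ")))
  })
  if ("dsc" %in% enabled) run_stage("dsc", function() {
    fits <- purrr::map(config$dsc, function(path) {
      analyze_thermogram(read_thermogram(path))
    })
    names(fits) <- basename(config$dsc)
    tab <- purrr::map_dfr(fits, glance, .id = "file")
    list(value = list(fits = fits, table = tab),
         detail = paste0("Tm: ", paste(sprintf("%.2f", tab$tm),
                                       collapse = ", "), " °C"))
  })
  report <- structure(c(results, list(summary = status)),
                      class = "memphys_report")
  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir, format = config$format %||% "tsv")
  }
  if (any(status$status == "error")) {
    abort(paste0("pipeline stage(s) failed: ",
                 paste(status$stage[status$status == "error"],
                       collapse = ", ")))
  }
  report
}

#' @export
print.memphys_report <- function(x, ...) {
  cat("memphys pipeline report\n")
  print(x$summary)
  invisible(x)
}

write_report <- function(report, out_dir, format = "tsv") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  flat <- report_tables(report)
  for (nm in names(flat)) {
    if (format == "json") {
      jsonlite::write_json(flat[[nm]], file.path(out_dir,
                                                 paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    } else {
      readr::write_tsv(flat[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    }
  }
  invisible(out_dir)
}

report_tables <- function(report) {
  out <- list(summary = report$summary)
  if (!is.null(report$motifs)) out$motifs <- report$motifs
  if (!is.null(report$hydropathy)) {
    out$hydropathy_profile <- report$hydropathy$profile
    out$hydropathy_segments <- report$hydropathy$segments
  }
  if (!is.null(report$disorder)) {
    out$disorder <- tibble(fraction = report$disorder$fraction,
                           threshold = report$disorder$threshold,
                           n_residues = report$disorder$n_residues)
    out$disorder_regions <- report$disorder$regions
  }
  if (!is.null(report$cd)) {
    out$cd_ratio <- dplyr::mutate(report$cd$ratio,
                                  shape = report$cd$shape$shape)
    dec <- report$cd$deconvolution
    out$cd_fractions <- tibble(class = names(dec$fractions),
                               fraction = unname(dec$fractions),
                               coefficient = unname(dec$coefficients))
  }
  for (nm in c("binding", "quenching")) {
    if (!is.null(report[[nm]])) out[[paste0(nm, "_fit")]] <-
        glance(report[[nm]])
  }
  if (!is.null(report$anisotropy)) out$anisotropy <- report$anisotropy
  if (!is.null(report$dsc)) out$dsc <- report$dsc$table
  out
}
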