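## Windowed interfacial hydropathy (Wimley-White scale) and disorder-profile
## summaries.

#' Wimley-White interfacial hydrophobicity scale
#'
#' Free energies of transfer (kcal/mol) of each residue from water to the
#' POPC bilayer interface, from the published whole-residue interfacial
#' scale (Wimley & White, Nat Struct Biol 1996). Negative values favor
#' partitioning into the interface. Protonation variants are resolved to the
#' standard neutral-pH choices: Asp and Glu charged, His neutral, Lys and
#' Arg charged.
#'
#' @format Named numeric vector, one entry per 20-letter residue code.
#' @export
ww_interfacial <- c(
  A = 0.17, R = 0.81, N = 0.42, D = 1.23, C = -0.24,
  Q = 0.58, E = 2.02, G = 0.01, H = 0.17, I = -0.31,
  L = -0.56, K = 0.99, M = -0.23, F = -1.13, P = 0.45,
  S = 0.13, T = 0.14, W = -1.87, Y = -0.94, V = 0.07
)

#' Windowed interfacial hydropathy profile
#'
#' Sums per-residue water-to-interface transfer free energies over a sliding
#' window and assigns each sum to the window's centre residue, the scheme
#' used by membrane-protein hydropathy servers. With the default odd window
#' of 19 residues, centres run from residue `offset + 9` to
#' `offset + L - 10`; terminal residues without a full window receive no
#' value (no padding).
#'
#' @param seqs A sequence table ([read_fasta()], [protein_table()]) or a
#'   single residue string.
#' @param scale Named numeric vector of per-residue transfer free energies
#'   (kcal/mol); default [ww_interfacial].
#' @param window_length Odd integer window width (default 19).
#' @param impute_x Logical (default `FALSE`): when `TRUE`, unknown residues
#'   `X` take the mean scale value; when `FALSE` they are an error.
#' @return A tibble with columns `sequence_id`, `center` (residue
#'   coordinate of the window centre), `dg` (windowed sum, kcal/mol) and
#'   `window_length`.
#' @examples
#' prof <- hydropathy_profile(protein_table("p", strrep("L", 25)))
#' head(prof)
#' @export
hydropathy_profile <- function(seqs, scale = ww_interfacial,
                               window_length = 19L, impute_x = FALSE) {
  if (is.character(seqs) && !is.data.frame(seqs)) {
    seqs <- protein_table(paste0("seq", seq_along(seqs)), seqs)
  }
  window_length <- as.integer(window_length)
  if (window_length < 1L || window_length %% 2L == 0L) {
    abort("window_length must be a positive odd integer")
  }
  if (!all(AA20 %in% names(scale))) {
    abort("hydropathy scale must cover all 20 standard residues")
  }
  offs <- if ("numbering_offset" %in% names(seqs)) seqs$numbering_offset else 1L
  offs <- rep_len(as.integer(offs), nrow(seqs))
  half <- window_length %/% 2L
  purrr::map2_dfr(seq_len(nrow(seqs)), offs, function(i, off) {
    res <- strsplit(seqs$residues[i], "")[[1]]
    n <- length(res)
    if (n < window_length) {
      abort(paste0("sequence '", seqs$id[i], "' (", n,
                   " residues) is shorter than the window (",
                   window_length, ")"))
    }
    vals <- unname(scale[res])
    if (anyNA(vals)) {
      if (!impute_x) {
        abort(paste0("sequence '", seqs$id[i],
                     "' contains X; set impute_x = TRUE to impute ",
                     "the mean scale value"))
      }
      vals[is.na(vals)] <- mean(scale)
    }
    windowed <- as.numeric(stats::filter(vals, rep(1, window_length),
                                         sides = 2))
    centers <- seq.int(half + 1L, n - half)
    tibble(sequence_id = seqs$id[i],
           center = centers + off - 1L,
           dg = windowed[centers],
           window_length = window_length)
  })
}

#' Call membrane-favorable segments from a hydropathy profile
#'
#' Finds maximal runs of window centres whose windowed transfer free energy
#' lies below a favorability threshold (default 0 kcal/mol: partitioning
#' into the interface releases free energy). Segment extent is reported in
#' centre-residue coordinates by default; `expand = TRUE` widens each run by
#' half the window on both sides (clipped to the sequence) to report
#' full-window coverage instead. The convention in use is recorded in the
#' `extent` column.
#'
#' @param profile A profile tibble from [hydropathy_profile()].
#' @param threshold Favorability threshold in kcal/mol (default 0); centres
#'   with `dg < threshold` are favorable.
#' @param min_centers Minimum run length in centres for a segment to be
#'   reported (default 1).
#' @param expand Logical: expand runs by half a window to full-window
#'   residue coverage.
#' @return A tibble with columns `sequence_id`, `start`, `end`, `n_centers`,
#'   `mean_dg`, `min_dg`, `extent` (`"center"` or `"window"`), sorted by
#'   start.
#' @examples
#' prof <- hydropathy_profile(protein_table("p", strrep("L", 30)))
#' call_segments(prof)
#' @export
call_segments <- function(profile, threshold = 0, min_centers = 1L,
                          expand = FALSE) {
  stopifnot(is.data.frame(profile),
            all(c("sequence_id", "center", "dg") %in% names(profile)))
  if (nrow(profile) == 0L) abort("empty hydropathy profile")
  half <- if ("window_length" %in% names(profile)) {
    profile$window_length[1] %/% 2L
  } else 0L
  out <- profile |>
    dplyr::group_by(.data$sequence_id) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$center)
      fav <- d$dg < threshold
      r <- rle(fav)
      ends_i <- cumsum(r$lengths)
      starts_i <- ends_i - r$lengths + 1L
      keep <- r$values & r$lengths >= min_centers
      if (!any(keep)) {
        return(tibble(start = integer(), end = integer(),
                      n_centers = integer(), mean_dg = numeric(),
                      min_dg = numeric()))
      }
      purrr::map2_dfr(starts_i[keep], ends_i[keep], function(a, b) {
        tibble(start = d$center[a], end = d$center[b],
               n_centers = b - a + 1L,
               mean_dg = mean(d$dg[a:b]), min_dg = min(d$dg[a:b]))
      })
    }) |>
    dplyr::ungroup()
  if (expand && nrow(out) > 0L) {
    lo <- profile |>
      dplyr::group_by(.data$sequence_id) |>
      dplyr::summarise(first_center = min(.data$center),
                       last_center = max(.data$center))
    out <- dplyr::left_join(out, lo, by = "sequence_id") |>
      dplyr::mutate(start = pmax(.data$start - half,
                                 .data$first_center - half),
                    end = pmin(.data$end + half, .data$last_center + half)) |>
      dplyr::select(-"first_center", -"last_center")
  }
  dplyr::mutate(dplyr::arrange(out, .data$sequence_id, .data$start),
                extent = if (expand) "window" else "center")
}

#' Read a per-residue disorder profile from TSV
#'
#' Ingests the two-column output of an external disorder predictor
#' (residue index, score in \[0, 1\]); the predictor itself is not part of
#' this package.
#'
#' @param path TSV path with columns `residue_index` and `score` (header
#'   required; extra columns ignored).
#' @param source Label for the predictor that produced the scores.
#' @return A tibble with columns `residue_index`, `score`, `source`.
#' @export
read_disorder_profile <- function(path, source = "external") {
  d <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("residue_index", "score") %in% names(d))) {
    abort("disorder profile TSV needs columns 'residue_index' and 'score'")
  }
  check_scores(d$score)
  tibble(residue_index = as.integer(d$residue_index),
         score = as.numeric(d$score), source = source)
}

check_scores <- function(score) {
  if (length(score) == 0L) abort("empty disorder profile")
  if (anyNA(score) || any(score < 0 | score > 1)) {
    abort("disorder scores must lie in [0, 1]")
  }
  invisible(TRUE)
}

#' Summarize a disorder profile: disordered fraction and regions
#'
#' Computes the fraction of residues at or above a disorder threshold on the
#' predictor's normalized 0 (ordered) to 1 (disordered) scale, together with
#' the maximal runs of above-threshold residues.
#'
#' @param profile A tibble with columns `residue_index` and `score`
#'   (e.g. from [read_disorder_profile()] or the `disorder_profile`
#'   generator scenario).
#' @param threshold Score threshold (default 0.5); residues with
#'   `score >= threshold` count as disordered.
#' @return A list with elements `fraction` (numeric in \[0, 1\]),
#'   `n_residues`, `threshold`, and `regions` (tibble `start`, `end`,
#'   `n_residues`, `max_score`).
#' @examples
#' prof <- tibble::tibble(residue_index = 1:10,
#'                        score = c(rep(0.8, 4), rep(0.1, 6)))
#' fraction_disordered(prof)$fraction
#' @export
fraction_disordered <- function(profile, threshold = 0.5) {
  stopifnot(is.data.frame(profile),
            all(c("residue_index", "score") %in% names(profile)))
  profile <- dplyr::arrange(profile, .data$residue_index)
  check_scores(profile$score)
  dis <- profile$score >= threshold
  r <- rle(dis)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- which(r$values)
  regions <- purrr::map_dfr(keep, function(k) {
    a <- starts_i[k]; b <- ends_i[k]
    tibble(start = profile$residue_index[a], end = profile$residue_index[b],
           n_residues = b - a + 1L, max_score = max(profile$score[a:b]))
  })
  if (length(keep) == 0L) {
    regions <- tibble(start = integer(), end = integer(),
                      n_residues = integer(), max_score = numeric())
  }
  list(fraction = mean(dis), n_residues = nrow(profile),
       threshold = threshold, regions = regions)
}
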