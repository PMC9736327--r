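## Cholesterol-recognition motif (CRAC/CARC) and caveolin-binding motif (CBM)
## consensus scanning with variable-length gaps.
##
## Consensus definitions, read N -> C:
##   CARC: (K/R) - X(1-5) - (Y/F) - X(1-5) - (L/V)
##   CRAC: (L/V) - X(1-5) - (Y/F) - X(1-5) - (K/R)   (the mirror of CARC)
##   CBM:  Phi - X(4) - Phi - X(2) - Phi, Phi aromatic {F, W, Y}; length 9
## X is any residue (including the unknown code X); anchor positions never
## accept X.

#' Motif consensus pattern
#'
#' Constructs one of the three built-in cholesterol/caveolin motif consensus
#' patterns. Each pattern has three anchor positions with allowed residue
#' sets, separated by two gaps with inclusive length ranges.
#'
#' The CARC centre position is `Y/F` as usually printed; some literature
#' variants also admit tryptophan, available via `carc_center_w = TRUE`
#' (applies to CRAC's centre too, since CRAC is the mirror consensus).
#'
#' @param motif_class One of `"carc"`, `"crac"`, `"cbm"`.
#' @param carc_center_w Logical (default `FALSE`): widen the CARC/CRAC centre
#'   aromatic set from \{Y, F\} to \{Y, F, W\}.
#' @return A list of class `motif_pattern` with elements `motif_class`,
#'   `sets` (list of three character vectors) and `gaps` (list of two
#'   `c(min, max)` integer ranges).
#' @examples
#' motif_pattern("carc")
#' @export
motif_pattern <- function(motif_class = c("carc", "crac", "cbm"),
                          carc_center_w = FALSE) {
  motif_class <- match.arg(motif_class)
  center <- if (carc_center_w) c("Y", "F", "W") else c("Y", "F")
  phi <- c("F", "W", "Y")
  pat <- switch(motif_class,
    carc = list(sets = list(c("K", "R"), center, c("L", "V")),
                gaps = list(c(1L, 5L), c(1L, 5L))),
    crac = list(sets = list(c("L", "V"), center, c("K", "R")),
                gaps = list(c(1L, 5L), c(1L, 5L))),
    cbm  = list(sets = list(phi, phi, phi),
                gaps = list(c(4L, 4L), c(2L, 2L)))
  )
  structure(c(list(motif_class = motif_class), pat), class = "motif_pattern")
}

#' Scan sequences for cholesterol-recognition and caveolin-binding motifs
#'
#' Slides each consensus over every sequence and reports every distinct
#' `(start, end)` span that admits at least one valid anchor parse, exactly
#' once, sorted by sequence, class, start, then end. Overlapping and nested
#' spans are all reported (no greedy suppression). The attached anchor parse
#' is the representative with the smallest first-gap length, ties broken by
#' the smallest second-gap length.
#'
#' Coordinates are 1-based inclusive in the numbering of the input table
#' (`numbering_offset` of each record).
#'
#' @param seqs A sequence table from [read_fasta()] or [protein_table()].
#' @param motifs Character vector of classes to scan, any of
#'   `"carc"`, `"crac"`, `"cbm"`.
#' @param carc_center_w Passed to [motif_pattern()].
#' @return A tibble with columns `sequence_id`, `motif_class`, `start`,
#'   `end`, `subsequence`, `anchors` (e.g. `"K81/Y85/L88"`), and the anchor
#'   coordinates `anchor1`, `anchor2`, `anchor3`. Zero rows when nothing
#'   matches.
#' @examples
#' frag <- protein_table("cav2_frag", "FEISKYVMYKFL", numbering_offset = 77)
#' scan_motifs(frag)
#' @export
scan_motifs <- function(seqs, motifs = c("carc", "crac", "cbm"),
                        carc_center_w = FALSE) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  motifs <- match.arg(motifs, several.ok = TRUE)
  offs <- if ("numbering_offset" %in% names(seqs)) seqs$numbering_offset else 1L
  offs <- rep_len(offs, nrow(seqs))
  rows <- purrr::pmap(
    list(seqs$id, seqs$residues, offs),
    function(id, res, off) {
      purrr::map(motifs, function(m) {
        h <- scan_one(res, motif_pattern(m, carc_center_w))
        if (nrow(h) == 0L) return(h)
        shift <- as.integer(off) - 1L
        h$start <- h$start + shift
        h$end <- h$end + shift
        h$anchor1 <- h$anchor1 + shift
        h$anchor2 <- h$anchor2 + shift
        h$anchor3 <- h$anchor3 + shift
        dplyr::mutate(h, sequence_id = id, motif_class = m, .before = 1)
      })
    }
  )
  hits <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(hits) == 0L) {
    return(tibble(sequence_id = character(), motif_class = character(),
                  start = integer(), end = integer(),
                  subsequence = character(), anchors = character(),
                  anchor1 = integer(), anchor2 = integer(),
                  anchor3 = integer()))
  }
  hits$subsequence <- substr_coord(seqs, hits)
  hits$anchors <- paste0(
    substr(hits$subsequence, 1L, 1L), hits$anchor1, "/",
    substr(hits$subsequence, hits$anchor2 - hits$start + 1L,
           hits$anchor2 - hits$start + 1L), hits$anchor2, "/",
    substr(hits$subsequence, hits$anchor3 - hits$start + 1L,
           hits$anchor3 - hits$start + 1L), hits$anchor3)
  dplyr::arrange(
    dplyr::select(hits, "sequence_id", "motif_class", "start", "end",
                  "subsequence", "anchors", "anchor1", "anchor2", "anchor3"),
    .data$sequence_id, .data$motif_class, .data$start, .data$end)
}

## core scanner in string-local (1-based) coordinates
scan_one <- function(residues, pattern) {
  chars <- strsplit(residues, "")[[1]]
  n <- length(chars)
  out <- list()
  g1r <- pattern$gaps[[1]]
  g2r <- pattern$gaps[[2]]
  starts <- which(chars %in% pattern$sets[[1]])
  for (i in starts) {
    for (g1 in seq.int(g1r[1], g1r[2])) {
      j <- i + g1 + 1L
      if (j > n || !chars[j] %in% pattern$sets[[2]]) next
      for (g2 in seq.int(g2r[1], g2r[2])) {
        k <- j + g2 + 1L
        if (k > n || !chars[k] %in% pattern$sets[[3]]) next
        key <- paste0(i, ":", k)
        if (is.null(out[[key]])) {
          out[[key]] <- c(i, k, i, j, k)  # first parse = smallest g1 then g2
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(start = integer(), end = integer(), anchor1 = integer(),
                  anchor2 = integer(), anchor3 = integer()))
  }
  m <- do.call(rbind, unname(out))
  tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
         anchor1 = as.integer(m[, 3]), anchor2 = as.integer(m[, 4]),
         anchor3 = as.integer(m[, 5]))
}

substr_coord <- function(seqs, hits) {
  lookup_res <- setNames(seqs$residues, seqs$id)
  off <- if ("numbering_offset" %in% names(seqs)) seqs$numbering_offset else
    rep(1L, nrow(seqs))
  lookup_off <- setNames(as.integer(off), seqs$id)
  unname(substr(lookup_res[hits$sequence_id],
                hits$start - lookup_off[hits$sequence_id] + 1L,
                hits$end - lookup_off[hits$sequence_id] + 1L))
}

#' Report overlaps between motif hits of different classes
#'
#' For each pair of hits of different motif class (from the same sequence)
#' whose spans intersect, reports the intersection interval and whether one
#' span fully contains the other. The caveolin-2 CARC (81-88) lying partly
#' inside the CBM (77-85) is the canonical example.
#'
#' @param hits A hit table from [scan_motifs()].
#' @return A tibble with one row per overlapping pair: `sequence_id`,
#'   `class_a`, `start_a`, `end_a`, `class_b`, `start_b`, `end_b`,
#'   `intersection_start`, `intersection_end`, `containment`.
#' @examples
#' frag <- protein_table("cav2_frag", "FEISKYVMYKFL", numbering_offset = 77)
#' overlap_report(scan_motifs(frag))
#' @export
overlap_report <- function(hits) {
  empty <- tibble(sequence_id = character(),
                  class_a = character(), start_a = integer(),
                  end_a = integer(), class_b = character(),
                  start_b = integer(), end_b = integer(),
                  intersection_start = integer(),
                  intersection_end = integer(), containment = logical())
  if (nrow(hits) < 2L) return(empty)
  pairs <- dplyr::inner_join(
    dplyr::rename_with(hits, ~ paste0(.x, "_a"),
                       !dplyr::all_of("sequence_id")),
    dplyr::rename_with(hits, ~ paste0(.x, "_b"),
                       !dplyr::all_of("sequence_id")),
    by = "sequence_id", relationship = "many-to-many")
  pairs <- dplyr::filter(
    pairs,
    .data$motif_class_a < .data$motif_class_b,  # unordered pairs, distinct class
    .data$start_a <= .data$end_b, .data$start_b <= .data$end_a)
  if (nrow(pairs) == 0L) return(empty)
  dplyr::transmute(
    pairs,
    sequence_id = .data$sequence_id,
    class_a = .data$motif_class_a, start_a = .data$start_a,
    end_a = .data$end_a,
    class_b = .data$motif_class_b, start_b = .data$start_b,
    end_b = .data$end_b,
    intersection_start = pmax(.data$start_a, .data$start_b),
    intersection_end = pmin(.data$end_a, .data$end_b),
    containment = (.data$start_a <= .data$start_b &
                     .data$end_b <= .data$end_a) |
      (.data$start_b <= .data$start_a & .data$end_a <= .data$end_b))
}

## Strong similarity groups (Clustal convention), used as the default for
## percent-similarity scoring over pairwise alignments.
SIMILARITY_GROUPS_STRONG <- list(
  c("S", "T", "A"), c("N", "E", "Q", "K"), c("N", "H", "Q", "K"),
  c("N", "D", "E", "Q"), c("Q", "H", "R", "K"), c("M", "I", "L", "V"),
  c("M", "I", "L", "F"), c("H", "Y"), c("F", "Y", "W"))

#' Percent identity and similarity of a pairwise alignment
#'
#' Summarizes a supplied pairwise alignment (two equal-length gapped strings;
#' gap symbol `-`). Columns where both sequences are gapped are excluded.
#' Identity counts columns with identical residues; similarity additionally
#' counts columns whose residues share a similarity group. Both are returned
#' on the 0-100 scale. This is a summarizer over an existing alignment, not
#' an aligner.
#'
#' @param aligned_a,aligned_b Equal-length gapped residue strings.
#' @param similarity_groups List of character vectors of grouped residues;
#'   defaults to the Clustal strong groups.
#' @return A tibble with columns `identity`, `similarity`, `n_columns`
#'   (scored columns).
#' @examples
#' identity_similarity("AC-T", "AG-T", similarity_groups = list(c("C", "G")))
#' @export
identity_similarity <- function(aligned_a, aligned_b,
                                similarity_groups = SIMILARITY_GROUPS_STRONG) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    abort("aligned sequences must have equal length")
  }
  a <- strsplit(toupper(aligned_a), "")[[1]]
  b <- strsplit(toupper(aligned_b), "")[[1]]
  scored <- !(a == "-" & b == "-")
  n <- sum(scored)
  if (n == 0L) {
    abort("alignment has no scored columns (all-gap vs all-gap)")
  }
  a <- a[scored]
  b <- b[scored]
  ident <- a == b & a != "-" & b != "-"
  same_group <- purrr::map_lgl(seq_along(a), function(i) {
    if (a[i] == "-" || b[i] == "-") return(FALSE)
    any(purrr::map_lgl(similarity_groups,
                       ~ a[i] %in% .x && b[i] %in% .x))
  })
  tibble(identity = 100 * sum(ident) / n,
         similarity = 100 * sum(ident | same_group) / n,
         n_columns = n)
}
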