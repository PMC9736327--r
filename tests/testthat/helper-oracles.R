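# Independent oracles used by property tests.

# Brute-force motif oracle: enumerate every substring and test every anchor
# placement, instead of the scanner's anchored sliding search.
brute_force_spans <- function(residues, motif_class, carc_center_w = FALSE) {
  chars <- strsplit(residues, "")[[1]]
  n <- length(chars)
  center <- if (carc_center_w) c("Y", "F", "W") else c("Y", "F")
  sets <- switch(motif_class,
    carc = list(c("K", "R"), center, c("L", "V")),
    crac = list(c("L", "V"), center, c("K", "R")),
    cbm  = list(c("F", "W", "Y"), c("F", "W", "Y"), c("F", "W", "Y")))
  gaps <- if (motif_class == "cbm") list(4:4, 2:2) else list(1:5, 1:5)
  spans <- list()
  for (start in seq_len(n)) {
    for (end in start:min(n, start + 12L)) {
      len <- end - start + 1L
      found <- FALSE
      for (g1 in gaps[[1]]) {
        g2 <- len - 3L - g1
        if (!g2 %in% gaps[[2]]) next
        a1 <- start
        a2 <- start + 1L + g1
        a3 <- end
        if (chars[a1] %in% sets[[1]] && chars[a2] %in% sets[[2]] &&
            chars[a3] %in% sets[[3]]) {
          found <- TRUE
          break
        }
      }
      if (found) spans[[length(spans) + 1L]] <- c(start, end)
    }
  }
  if (length(spans) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  m <- unique(do.call(rbind, spans))
  out <- data.frame(start = m[, 1], end = m[, 2])
  out[order(out$start, out$end), , drop = FALSE]
}

# random sequences with enough anchor residues to produce hits
random_protein <- function(n, anchor_rich = TRUE) {
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (anchor_rich) {
    w <- ifelse(alphabet %in% c("K", "R", "Y", "F", "L", "V", "W"), 3, 1)
  } else {
    w <- rep(1, length(alphabet))
  }
  paste(sample(alphabet, n, replace = TRUE, prob = w / sum(w)),
        collapse = "")
}

# direct per-window summation, no stats::filter
direct_window_sums <- function(residues, scale, w) {
  chars <- strsplit(residues, "")[[1]]
  v <- unname(scale[chars])
  n <- length(v)
  half <- w %/% 2
  vapply(seq.int(half + 1L, n - half),
         function(c) sum(v[(c - half):(c + half)]), numeric(1))
}

write_temp_fasta <- function(records) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(unlist(purrr::imap(records,
                                ~ c(paste0(">", .y), .x))), path)
  path
}
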