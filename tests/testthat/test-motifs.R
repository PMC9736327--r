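test_that("FASTA round-trips records, uppercases, and validates the alphabet", {
  path <- write_temp_fasta(list(a = "acdefghik", b = c("LMNPQRST", "VWY")))
  seqs <- read_fasta(path)
  expect_equal(seqs$id, c("a", "b"))
  expect_equal(seqs$residues, c("ACDEFGHIK", "LMNPQRSTVWY"))
  expect_equal(seqs$length, c(9L, 11L))
  expect_equal(seqs$numbering_offset, c(1L, 1L))

  bad <- write_temp_fasta(list(rec1 = "ACDB"))
  expect_error(read_fasta(bad), "position 4.*rec1|rec1.*position 4")

  gapped <- write_temp_fasta(list(aln = "AC-DE"))
  expect_error(read_fasta(gapped), "gap")

  dup <- write_temp_fasta(list(x = "ACD", x = "ACE"))
  expect_error(read_fasta(dup), "duplicate")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_error(read_fasta(empty), "no records")
})

test_that("the printed caveolin-2 fragment yields the CARC and CBM hits", {
  frag <- protein_table("cav2_frag", "FEISKYVMYKFL", numbering_offset = 77)
  hits <- scan_motifs(frag)

  carc <- dplyr::filter(hits, motif_class == "carc")
  expect_equal(nrow(carc), 1L)
  expect_equal(carc$start, 81L)
  expect_equal(carc$end, 88L)
  expect_equal(carc$subsequence, "KYVMYKFL")
  expect_equal(carc$anchors, "K81/Y85/L88")

  cbm <- dplyr::filter(hits, motif_class == "cbm")
  expect_equal(nrow(cbm), 1L)
  expect_equal(cbm$start, 77L)
  expect_equal(cbm$end, 85L)
  expect_equal(cbm$subsequence, "FEISKYVMY")
  expect_equal(cbm$anchors, "F77/Y82/Y85")

  expect_equal(nrow(dplyr::filter(hits, motif_class == "crac")), 0L)
})

test_that("sequences without anchors, and X anywhere, never match anchors", {
  none <- protein_table("poly_a", "AAAAAAAAAA")
  expect_equal(nrow(scan_motifs(none)), 0L)

  # X works inside gaps but never as an anchor
  gaps_x <- protein_table("gx", "KXXXYXXL")
  h <- scan_motifs(gaps_x, motifs = "carc")
  expect_equal(h$start, 1L)
  expect_equal(h$end, 8L)
  anchor_x <- protein_table("ax", "XAAAYAAL")
  expect_equal(nrow(scan_motifs(anchor_x, motifs = "carc")), 0L)
})

test_that("scanner span sets match the brute-force oracle on random sequences", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    seqstr <- random_protein(n)
    seqs <- protein_table("r", seqstr)
    for (cls in c("carc", "crac", "cbm")) {
      got <- scan_motifs(seqs, motifs = cls)
      want <- brute_force_spans(seqstr, cls)
      expect_equal(got$start, want$start,
                   info = paste(cls, seqstr))
      expect_equal(got$end, want$end, info = paste(cls, seqstr))
    }
  }
})

test_that("reversing a sequence maps CARC hits onto CRAC hits", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    seqstr <- random_protein(n)
    rev_str <- paste(rev(strsplit(seqstr, "")[[1]]), collapse = "")
    carc <- scan_motifs(protein_table("f", seqstr), motifs = "carc")
    crac <- scan_motifs(protein_table("r", rev_str), motifs = "crac")
    mirrored <- sort(n + 1L - carc$end)
    expect_equal(sort(crac$start), mirrored)
    expect_equal(sort(crac$end), sort(n + 1L - carc$start))
  }
})

test_that("matched subsequences round-trip through coordinates", {
  set.seed(11)
  seqstr <- random_protein(60)
  seqs <- protein_table("s", seqstr, numbering_offset = 101)
  hits <- scan_motifs(seqs)
  for (i in seq_len(nrow(hits))) {
    expect_equal(hits$subsequence[i],
                 substr(seqstr, hits$start[i] - 100L, hits$end[i] - 100L))
    a2 <- substr(seqstr, hits$anchor2[i] - 100L, hits$anchor2[i] - 100L)
    expect_true(a2 %in% unlist(motif_pattern(hits$motif_class[i])$sets[2]))
  }
})

test_that("representative parse minimizes the first gap, then the second", {
  # K A Y A Y A L: anchor2 can be Y3 (g1=1) or Y5 (g1=3); both end at L7
  h <- scan_motifs(protein_table("p", "KAYAYAL"), motifs = "carc")
  expect_equal(nrow(h), 1L)
  expect_equal(h$anchor2, 3L)
})

test_that("the CARC centre widens to W only when asked", {
  s <- protein_table("w", "KAAWAAL")
  expect_equal(nrow(scan_motifs(s, motifs = "carc")), 0L)
  expect_equal(nrow(scan_motifs(s, motifs = "carc", carc_center_w = TRUE)),
               1L)
})

test_that("overlap report gives intersections and containment flags", {
  frag <- protein_table("cav2_frag", "FEISKYVMYKFL", numbering_offset = 77)
  ov <- overlap_report(scan_motifs(frag))
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$intersection_start, 81L)
  expect_equal(ov$intersection_end, 85L)
  expect_false(ov$containment)

  # disjoint hits of different class
  far <- protein_table("far", paste0("KAYAL", strrep("A", 20), "FAAAAYAAY"))
  expect_equal(nrow(overlap_report(scan_motifs(far))), 0L)

  # nested: CBM 1-9 inside CARC 1-11 (K1..Y6..L11 vs F? need aromatic start)
  nested <- protein_table("n", "YAAAAYAAYVL")
  # carc needs K/R; craft crac instead: V? use hits built by hand
  hits <- tibble::tibble(
    sequence_id = "h", motif_class = c("carc", "cbm"),
    start = c(10L, 12L), end = c(22L, 20L),
    subsequence = c("x", "y"), anchors = c("", ""),
    anchor1 = c(10L, 12L), anchor2 = c(15L, 17L), anchor3 = c(22L, 20L))
  ov2 <- overlap_report(hits)
  expect_true(ov2$containment)
  expect_equal(c(ov2$intersection_start, ov2$intersection_end), c(12L, 20L))
})

test_that("identity and similarity summarize pairwise alignments", {
  self <- identity_similarity("MKVL", "MKVL")
  expect_equal(self$identity, 100)
  expect_equal(self$similarity, 100)

  r <- identity_similarity("AC-T", "AG-T",
                           similarity_groups = list(c("C", "G")))
  expect_equal(r$identity, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(r$similarity, 100)
  expect_equal(r$n_columns, 3L)

  expect_error(identity_similarity("AC", "ACG"), "equal length")
  expect_error(identity_similarity("--", "--"), "no scored columns")

  # default strong groups: L/V are grouped, L/D are not
  d <- identity_similarity("LD", "VD")
  expect_equal(d$identity, 50)
  expect_equal(d$similarity, 100)
})
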