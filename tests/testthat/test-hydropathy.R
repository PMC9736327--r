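test_that("homopolymer and single-window profiles match closed forms", {
  prof <- hydropathy_profile(protein_table("polyL", strrep("L", 30)))
  expect_equal(unique(prof$dg), 19 * ww_interfacial[["L"]])
  expect_equal(nrow(prof), 30 - 19 + 1)
  expect_equal(prof$center, 10:21)

  mer <- protein_table("m19", "ACDEFGHIKLMNPQRSTVW")
  p1 <- hydropathy_profile(mer)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$center, 10L)
  expect_equal(p1$dg,
               sum(ww_interfacial[strsplit("ACDEFGHIKLMNPQRSTVW", "")[[1]]]))
})

test_that("windowed values equal brute-force per-window sums", {
  set.seed(5)
  for (rep in 1:8) {
    seqstr <- random_protein(50, anchor_rich = FALSE)
    prof <- hydropathy_profile(protein_table("r", seqstr))
    expect_equal(prof$dg, direct_window_sums(seqstr, ww_interfacial, 19))
  }
  # and for a non-default window
  seqstr <- random_protein(40, anchor_rich = FALSE)
  prof7 <- hydropathy_profile(protein_table("r", seqstr), window_length = 7)
  expect_equal(prof7$dg, direct_window_sums(seqstr, ww_interfacial, 7))
})

test_that("short sequences and unknown residues are rejected, X imputable", {
  expect_error(hydropathy_profile(protein_table("s", "ACDEF")),
               "shorter than the window")
  withx <- protein_table("x", paste0(strrep("L", 10), "X", strrep("L", 10)))
  expect_error(hydropathy_profile(withx), "impute_x")
  prof <- hydropathy_profile(withx, impute_x = TRUE)
  mid <- prof$dg[prof$center == 11]
  expect_equal(mid, 18 * ww_interfacial[["L"]] + mean(ww_interfacial))
  expect_error(hydropathy_profile(protein_table("ok", strrep("L", 25)),
                                  window_length = 10),
               "odd")
})

test_that("segment calling finds maximal favorable runs", {
  allfav <- hydropathy_profile(protein_table("f", strrep("F", 40)))
  seg <- call_segments(allfav)
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$start, seg$end), range(allfav$center))
  expect_equal(seg$min_dg, 19 * ww_interfacial[["F"]])

  # alternating favorable/unfavorable centers with min_centers 2 -> nothing
  prof <- tibble::tibble(sequence_id = "alt", center = 1:10,
                         dg = rep(c(-1, 1), 5), window_length = 1L)
  expect_equal(nrow(call_segments(prof, min_centers = 2)), 0L)
  expect_equal(nrow(call_segments(prof, min_centers = 1)), 5L)
})

test_that("segment calls are stable under unfavorable flanking sequence", {
  # termini already unfavorable, so the favorable/unfavorable boundary
  # windows are identical before and after adding more flank
  core <- paste0(strrep("E", 10), strrep("F", 25), strrep("E", 10))
  base <- call_segments(hydropathy_profile(protein_table("c", core)))
  expect_equal(nrow(base), 1L)
  cflank <- call_segments(hydropathy_profile(
    protein_table("cf", paste0(core, strrep("E", 15)))))
  expect_equal(cflank$start, base$start)
  expect_equal(cflank$end, base$end)
  nflank <- call_segments(hydropathy_profile(
    protein_table("nf", paste0(strrep("E", 15), core))))
  expect_equal(nflank$start - 15L, base$start)
  expect_equal(nflank$end - 15L, base$end)
})

test_that("window-extent expansion widens runs by half a window, clipped", {
  prof <- hydropathy_profile(protein_table("f", strrep("F", 40)))
  seg <- call_segments(prof, expand = TRUE)
  expect_equal(seg$extent, "window")
  expect_equal(c(seg$start, seg$end), c(1L, 40L))
})

test_that("disorder summaries count thresholded residues and regions", {
  zero <- tibble::tibble(residue_index = 1:50, score = 0)
  s0 <- fraction_disordered(zero)
  expect_equal(s0$fraction, 0)
  expect_equal(nrow(s0$regions), 0L)
  expect_equal(fraction_disordered(zero, threshold = 0)$fraction, 1)

  set.seed(3)
  scores <- runif(100, 0, 0.49)
  idx <- sample(100, 46)
  scores[idx] <- runif(46, 0.5, 1)
  prof <- tibble::tibble(residue_index = 1:100, score = scores)
  s <- fraction_disordered(prof)
  expect_equal(s$fraction, 0.46)
  expect_equal(sum(s$regions$n_residues), 46L)
  expect_true(all(s$regions$max_score >= 0.5))

  expect_error(fraction_disordered(
    tibble::tibble(residue_index = 1, score = 1.2)), "\\[0, 1\\]")
})

test_that("disordered fraction is monotone non-increasing in the threshold", {
  set.seed(9)
  prof <- tibble::tibble(residue_index = 1:200, score = runif(200))
  ths <- seq(0, 1, by = 0.1)
  fr <- vapply(ths, function(t) fraction_disordered(prof, t)$fraction,
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("disorder TSV ingestion validates its columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("residue_index\tscore", "1\t0.7", "2\t0.2"), path)
  prof <- read_disorder_profile(path, source = "predictor")
  expect_equal(prof$score, c(0.7, 0.2))
  expect_equal(prof$source, rep("predictor", 2))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pos\tval", "1\t0.7"), bad)
  expect_error(read_disorder_profile(bad), "residue_index")
})
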