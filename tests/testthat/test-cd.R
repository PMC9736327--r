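# spectrum with exact ellipticities at chosen knots, linear in between
knot_spectrum <- function(knots, grid = 200:250) {
  tibble::tibble(wavelength = as.numeric(grid),
                 ellipticity = approx(knots$wl, knots$y, xout = grid)$y)
}

test_that("mean residue ellipticity conversion follows the standard formula", {
  raw <- tibble::tibble(wavelength = 200:250, ellipticity = 0)
  expect_equal(to_mean_residue_ellipticity(raw, 0.01, 64e-6, 162)$ellipticity,
               rep(0, 51))

  raw$ellipticity <- seq(-5, 5, length.out = 51)
  a <- to_mean_residue_ellipticity(raw, 0.01, 64e-6, 162)
  b <- to_mean_residue_ellipticity(raw, 0.01, 128e-6, 162)
  expect_equal(a$ellipticity, 2 * b$ellipticity)

  # 10 mdeg in a 0.1 mm cuvette, 64 uM protein, 162 residues
  one <- tibble::tibble(wavelength = c(210, 211), ellipticity = c(10, 10))
  mre <- to_mean_residue_ellipticity(one, 0.01, 64e-6, 162)$ellipticity[1]
  expect_equal(mre, 10 / (10 * 0.01 * 64e-6 * 162), tolerance = 1e-12)

  expect_error(to_mean_residue_ellipticity(one, 0, 64e-6, 162), "positive")
})

test_that("theta222/theta208 ratio reproduces the coiled-coil diagnostic", {
  iso <- knot_spectrum(list(wl = c(200, 208, 215, 222, 250),
                            y = c(0, -10, -7, -9.6, 0)))
  r1 <- helix_ratio(iso)
  expect_equal(r1$ratio, 0.96, tolerance = 1e-12)
  expect_equal(r1$classification, "isolated_helices")

  cc <- knot_spectrum(list(wl = c(200, 208, 215, 222, 250),
                           y = c(0, -10, -8, -11.2, 0)))
  r2 <- helix_ratio(cc)
  expect_equal(r2$ratio, 1.12, tolerance = 1e-12)
  expect_equal(r2$classification, "coiled_coil")

  # boundary: ratio exactly 1 is NOT a coiled coil (strict >)
  eq <- knot_spectrum(list(wl = c(200, 208, 222, 250), y = c(0, -9, -9, 0)))
  r3 <- helix_ratio(eq)
  expect_equal(r3$ratio, 1)
  expect_equal(r3$classification, "isolated_helices")

  # positive ellipticity at a minimum position -> ratio undefined
  pos <- knot_spectrum(list(wl = c(200, 208, 222, 250), y = c(1, 2, 3, 4)))
  r4 <- helix_ratio(pos)
  expect_true(is.na(r4$ratio))
  expect_equal(r4$classification, "other")

  expect_error(helix_ratio(tibble::tibble(wavelength = 210:220,
                                          ellipticity = -1)),
               "cover")
})

test_that("the ratio is invariant to positive rescaling of the spectrum", {
  s <- synthetic_helix_spectrum(depth208 = -10, depth222 = -9.2)
  base <- helix_ratio(s)
  for (k in c(0.01, 3, 1000)) {
    scaled <- dplyr::mutate(s, ellipticity = ellipticity * k)
    expect_equal(helix_ratio(scaled)$ratio, base$ratio, tolerance = 1e-12)
  }
})

test_that("spectral shapes classify as w, v, or other", {
  w <- synthetic_helix_spectrum(depth208 = -10, depth222 = -9)
  expect_equal(classify_shape(w)$shape, "w_shaped")

  v <- tibble::tibble(wavelength = 200:250,
                      ellipticity = -8 * exp(-((200:250 - 218) / 8)^2))
  expect_equal(classify_shape(v)$shape, "v_shaped")

  mono <- tibble::tibble(wavelength = 200:250,
                         ellipticity = seq(-5, 5, length.out = 51))
  expect_equal(classify_shape(mono)$shape, "other")
})

test_that("deconvolution recovers pure members and exact mixtures", {
  basis <- cd_basis_default()
  pure <- tibble::tibble(wavelength = basis$wavelength,
                         ellipticity = basis$regular_helix)
  d <- deconvolve_cd(pure, basis)
  expect_equal(unname(d$fractions["regular_helix"]), 1, tolerance = 1e-8)
  expect_lt(d$residual_norm, 1e-8)

  mix <- tibble::tibble(
    wavelength = basis$wavelength,
    ellipticity = 0.6 * basis$regular_helix + 0.4 * basis$other)
  dm <- deconvolve_cd(mix, basis)
  expect_equal(unname(dm$fractions[c("regular_helix", "other")]),
               c(0.6, 0.4), tolerance = 1e-6)
  expect_lt(dm$residual_norm, 1e-8)

  degenerate <- tibble::tibble(wavelength = basis$wavelength,
                               a = basis$regular_helix,
                               b = 2 * basis$regular_helix)
  expect_error(deconvolve_cd(pure, degenerate), "collinear")
})

test_that("fractions are a point on the simplex for arbitrary spectra", {
  set.seed(21)
  basis <- cd_basis_default()
  for (rep in 1:10) {
    y <- rnorm(nrow(basis), sd = 10)
    d <- deconvolve_cd(tibble::tibble(wavelength = basis$wavelength,
                                      ellipticity = y), basis)
    expect_true(all(d$fractions >= 0))
    expect_equal(sum(d$fractions), 1, tolerance = 1e-12)
  }
})

test_that("simplex mixtures are recovered within 0.05 MAE at 2% noise", {
  basis <- cd_basis_default()
  classes <- setdiff(names(basis), "wavelength")
  A <- as.matrix(basis[classes])
  err <- numeric(50)
  set.seed(100)
  for (i in 1:50) {
    fr <- as.numeric(rexp(length(classes)))
    fr <- fr / sum(fr)
    y <- as.numeric(A %*% fr)
    y <- y + rnorm(length(y), sd = 0.02 * max(abs(y)))
    d <- deconvolve_cd(tibble::tibble(wavelength = basis$wavelength,
                                      ellipticity = y), basis)
    err[i] <- mean(abs(d$fractions[classes] - fr))
  }
  expect_lt(mean(err), 0.05)
})

test_that("spectrum files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".tsv")
  s <- synthetic_helix_spectrum()
  writeLines(c("# label: demo", "wavelength_nm\tellipticity",
               paste(s$wavelength, s$ellipticity, sep = "\t")), path)
  got <- read_cd_spectrum(path)
  expect_equal(got$wavelength, s$wavelength)
  expect_equal(got$ellipticity, s$ellipticity)
})
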