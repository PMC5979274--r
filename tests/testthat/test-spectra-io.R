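test_that("CSV reader canonicalises order and tolerates headers", {
  grid <- seq(1000, 1014, by = 2)
  vals <- c(0.1, 0.2, 0.1, 0.3, 0.2, 0.1, 0.4, 0.1)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(sprintf("%g,%g", grid, vals), f)
  s <- readSpectrumCSV(f, "WT", "W1", "1")
  expect_equal(wavenumbers(s), grid)
  expect_equal(absorbance(s), vals)

  # the same file written high-to-low reads identically
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(sprintf("%g,%g", rev(grid), rev(vals)), f2)
  s2 <- readSpectrumCSV(f2, "WT", "W1", "1")
  expect_equal(wavenumbers(s2), wavenumbers(s))
  expect_equal(absorbance(s2), absorbance(s))

  # instrument-sized export with a header line: 4000 -> 700 at 2 cm-1
  grid <- seq(700, 4000, by = 2)
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber,absorbance",
               sprintf("%g,%g", rev(grid), seq_along(grid) / 1e4)), f3)
  s3 <- readSpectrumCSV(f3)
  expect_length(wavenumbers(s3), 1651L)
})

test_that("CSV reader rejects malformed and degenerate input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1000,0.1", "1002,oops", "1004,0.1", "1006,0.1",
               "1008,0.1", "1010,0.1", "1012,0.1", "1014,0.1"), f)
  expect_error(readSpectrumCSV(f), "line 2")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(sprintf("%d,0.1", seq(1000, 1006, 2)), f2)
  expect_error(readSpectrumCSV(f2), "degenerate")
})

test_that("spectrum write/read round trip is the identity", {
  grid <- seq(900, 1100, by = 2)
  s <- bandSpectrum(grid, 1000, 15, 0.4, slope = 1e-4)
  f <- withr::local_tempfile(fileext = ".csv")
  writeSpectrumCSV(s, f)
  expect_error(writeSpectrumCSV(s, f), "exists")
  s2 <- readSpectrumCSV(f)
  expect_equal(wavenumbers(s2), wavenumbers(s))
  expect_equal(absorbance(s2), absorbance(s), tolerance = 1e-10)
})

test_that("JCAMP-DX reader agrees with the CSV dialect", {
  grid <- seq(1000, 1018, by = 2)
  y <- round(gauss(grid, 1008, 5, 0.3), 6)
  f <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=synthetic test spectrum",
    "##JCAMP-DX=4.24",
    "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
    "##XFACTOR=1", "##YFACTOR=0.000001",
    "##DELTAX=2",
    "##XYDATA=(X++(Y..Y))",
    paste(grid[1], paste(round(y[1:5] * 1e6), collapse = " ")),
    paste(grid[6], paste(round(y[6:10] * 1e6), collapse = " ")),
    "##END="
  ), f)
  s <- readJCAMPDX(f)
  expect_equal(wavenumbers(s), grid)
  expect_equal(absorbance(s), y, tolerance = 1e-9)
})

test_that("alignToGrid is idempotent and exact on linear spectra", {
  grid <- seq(1000, 1100, by = 4)
  s1 <- IRSpectrum(grid, grid / 1000, "WT", "W1", "1")
  s2 <- IRSpectrum(grid, grid / 2000, "WT", "W1", "2")
  set <- alignToGrid(list(s1, s2), spacing = 4)
  set2 <- alignToGrid(set, spacing = 4)
  expect_equal(absorbance(set2), absorbance(set))
  expect_equal(wavenumbers(set2), wavenumbers(set))

  # linear data resampled from 2 to 4 cm-1 stays exactly linear
  fine <- seq(1000, 1100, by = 2)
  sf <- IRSpectrum(fine, fine / 1000, "WT", "W2", "1")
  coarse <- alignToGrid(list(sf), spacing = 4)
  expect_equal(as.vector(absorbance(coarse)), wavenumbers(coarse) / 1000)
})

test_that("alignToGrid preserves band area across resampling", {
  fine <- seq(900, 1100, by = 2)
  s <- bandSpectrum(fine, 1000, 12, 0.5)
  res <- alignToGrid(list(s), spacing = 1)
  a_src <- pracma::trapz(fine, absorbance(s))
  a_res <- pracma::trapz(wavenumbers(res), as.vector(absorbance(res)))
  expect_lt(abs(a_res - a_src) / a_src, 0.005)
})

test_that("alignToGrid names the spectrum that lacks coverage", {
  s1 <- IRSpectrum(seq(1000, 1100, 2), rnorm(51), "WT", "W1", "1")
  s2 <- IRSpectrum(seq(1020, 1100, 2), rnorm(41), "WT", "W9", "1")
  expect_error(alignToGrid(list(s1, s2), range = c(1000, 1100)), "W9")
})

test_that("feature tables round-trip through CSV to 12 significant digits", {
  ft <- data.frame(genotype = "WT", sample_id = "W1", subsample_id = "1",
                   TC1 = pi / 10, AA = exp(1) * 13,
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(ft, f)
  expect_error(writeFeatureTable(ft, f), "exists")
  back <- readFeatureTable(f)
  expect_equal(nrow(back), 1L)
  expect_equal(back$TC1, ft$TC1, tolerance = 1e-12)
  expect_equal(back$AA, ft$AA, tolerance = 1e-12)
  expect_identical(names(back), names(ft))
})

test_that("spectrum set construction enforces the shared grid and design", {
  s1 <- IRSpectrum(1:10, rnorm(10), "WT", "W1", "1")
  s2 <- IRSpectrum(1:9, rnorm(9), "WT", "W1", "2")
  expect_error(IRSpectrumSet(list(s1, s2)), "share one")
  s3 <- IRSpectrum(1:10, rnorm(10), "WT", "W1", "1")
  expect_error(IRSpectrumSet(list(s1, s3)), "unique")
})
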