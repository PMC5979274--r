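# The core bespoke computation: two-point baselines, located peaks,
# corrected heights and trapezoidal areas, splits, per-observation ratios.

test_that("baselineValue interpolates linearly between region endpoints", {
  grid <- seq(941, 1484, by = 0.5)  # contains both endpoints exactly
  a <- seq(0, 0.543, length.out = length(grid))
  s <- IRSpectrum(grid, a)
  region <- c(1484, 941)

  # flat baseline
  s_flat <- IRSpectrum(grid, rep(0.2, length(grid)))
  expect_equal(baselineValue(s_flat, region, c(1000, 1212.5, 1400)),
               rep(0.2, 3))

  # endpoints 0 and 0.543 -> linear midpoint is their mean
  s_lin <- IRSpectrum(grid, rev(a))  # 0.543 at 941, 0 at 1484
  expect_equal(baselineValue(s_lin, region, (941 + 1484) / 2), 0.2715)

  # the baseline meets the spectrum at both endpoints, whatever the shape
  set.seed(4)
  s_rnd <- IRSpectrum(grid, runif(length(grid)))
  expect_equal(baselineValue(s_rnd, region, 941),
               absorbance(s_rnd)[1L])
  expect_equal(baselineValue(s_rnd, region, 1484),
               absorbance(s_rnd)[length(grid)])

  expect_error(baselineValue(s_rnd, region, 1600), "outside region")
})

test_that("locatePeak finds apices, resolves merged bands, falls back", {
  grid <- seq(940, 1178, by = 2)  # even nodes, so 1026 is on the grid
  s <- bandSpectrum(grid, 1026, 10, 0.6)
  expect_equal(locatePeak(s, nominal = 1026, mode = "apex"), 1026)
  expect_equal(locatePeak(s, nominal = 1030, mode = "apex",
                          halfwidth = 8), 1026)

  # two Gaussians at 1074/1104 with sigma 15 merge into one visible band;
  # the second derivative still shows two minima within +/-4 cm-1
  sm <- bandSpectrum(grid, c(1074, 1104), c(15, 15), c(0.5, 0.45))
  apex <- which.max(absorbance(sm))
  expect_lt(sum(diff(sign(diff(absorbance(sm)))) == -2), 2)  # single apex
  d2 <- secondDerivative(sm)
  loc74 <- locatePeak(sm, d2, 1074, "second_derivative")
  loc04 <- locatePeak(sm, d2, 1104, "second_derivative")
  expect_lte(abs(loc74 - 1074), 4)
  expect_lte(abs(loc04 - 1104), 4)

  # flat spectrum: no interior extremum -> nominal returned
  flat <- IRSpectrum(grid, rep(0.3, length(grid)))
  expect_equal(locatePeak(flat, nominal = 1026, mode = "apex"), 1026)
  expect_error(locatePeak(s, nominal = 945, mode = "apex"), "outside")
})

test_that("correctedHeight subtracts the baseline and warns when negative", {
  grid <- seq(900, 1100, by = 2)
  region <- c(1080, 920)
  # spectrum identical to its own baseline -> zero height everywhere
  s_line <- IRSpectrum(grid, 0.001 * grid + 0.05)
  expect_equal(correctedHeight(s_line, region, 1000), 0)

  s <- bandSpectrum(grid, 1000, 12, 0.3)
  expect_equal(correctedHeight(s, region, 1000), 0.3, tolerance = 1e-6)
  s_tilt <- IRSpectrum(grid, absorbance(s) + 0.001 * grid + 0.05)
  expect_equal(correctedHeight(s_tilt, region, 1000), 0.3,
               tolerance = 1e-6)

  dip <- IRSpectrum(grid, -absorbance(s))
  expect_warning(h <- correctedHeight(dip, region, 1000), "negative")
  expect_lt(h, 0)
})

test_that("correctedArea matches closed forms and a fine Riemann oracle", {
  # triangle (1000,0)-(1010,1)-(1020,0) on a zero baseline: area 10
  grid <- seq(960, 1060, by = 2)
  tri <- pmax(0, 1 - abs(grid - 1010) / 10)
  s_tri <- IRSpectrum(grid, tri)
  expect_equal(correctedArea(s_tri, c(1060, 960)), 10)

  # Gaussian amplitude 0.5, sigma 10 -> A sigma sqrt(2 pi)
  grid2 <- seq(900, 1100, by = 2)
  s_g <- bandSpectrum(grid2, 1000, 10, 0.5)
  expect_lt(abs(correctedArea(s_g, c(1100, 900)) -
                  0.5 * 10 * sqrt(2 * pi)) / (0.5 * 10 * sqrt(2 * pi)),
            0.001)

  # brute-force oracle: 10x finer trapezoid on a smooth band mixture
  s_mix <- bandSpectrum(grid2, c(950, 1020), c(12, 18), c(0.4, 0.7),
                        slope = 2e-4, intercept = 0.01)
  fine <- seq(900, 1100, by = 0.2)
  af <- approx(wavenumbers(s_mix), absorbance(s_mix), xout = fine)$y
  blf <- approx(c(900, 1100),
                absorbance(s_mix)[c(1, length(grid2))], xout = fine)$y
  oracle <- pracma::trapz(fine, af - blf)
  expect_lt(abs(correctedArea(s_mix, c(1100, 900)) - oracle) /
              abs(oracle), 0.005)

  expect_error(correctedArea(s_g, c(1000, 1000.5)), "degenerate")
})

test_that("corrected heights and areas are baseline-invariant", {
  set.seed(11)
  grid <- seq(900, 1100, by = 2)
  region <- c(1090, 910)
  for (i in 1:5) {
    s <- bandSpectrum(grid, runif(2, 950, 1050), runif(2, 8, 20),
                      runif(2, 0.1, 0.8))
    a <- rnorm(1, 0, 0.01)
    b <- rnorm(1, 0, 0.5)
    s_lin <- IRSpectrum(grid, absorbance(s) + a * grid + b)
    expect_lt(abs(correctedArea(s_lin, region) - correctedArea(s, region)),
              1e-9)
    at <- 1000
    expect_lt(abs(suppressWarnings(correctedHeight(s_lin, region, at)) -
                    suppressWarnings(correctedHeight(s, region, at))),
              1e-9)
  }
})

test_that("heights and areas scale linearly with band amplitude", {
  grid <- seq(900, 1100, by = 2)
  region <- c(1090, 910)
  s1 <- bandSpectrum(grid, c(960, 1030), c(10, 15), c(0.2, 0.5))
  for (k in c(0.5, 2, 7)) {
    sk <- IRSpectrum(grid, k * absorbance(s1))
    expect_equal(correctedArea(sk, region), k * correctedArea(s1, region),
                 tolerance = 1e-12)
    expect_equal(correctedHeight(sk, region, 1030),
                 k * correctedHeight(s1, region, 1030), tolerance = 1e-12)
  }
})

test_that("splitArea halves symmetric bands and is exactly additive", {
  grid <- seq(1484, 1710, by = 2)[order(seq(1484, 1710, by = 2))]
  region <- c(1710, 1484)
  # band centred exactly on the split node
  s_sym <- bandSpectrum(grid, 1576, 15, 0.5)
  parts <- splitArea(s_sym, region, 1576)
  expect_equal(parts[["high"]], parts[["low"]], tolerance = 1e-6)

  set.seed(3)
  s_rnd <- IRSpectrum(grid, runif(length(grid)))
  p <- splitArea(s_rnd, region, 1575)
  expect_equal(p[["high"]] + p[["low"]], correctedArea(s_rnd, region),
               tolerance = 1e-12)

  # band entirely above the cut leaves the low part ~ 0
  s_hi <- bandSpectrum(grid, 1660, 8, 0.5)
  p_hi <- splitArea(s_hi, region, 1575)
  expect_lt(abs(p_hi[["low"]]), 1e-6)
  expect_error(splitArea(s_hi, region, 1484), "strictly inside")
})

test_that("ratios are appended per observation with a zero guard", {
  sch <- defaultAlfalfaScheme()
  row <- as.data.frame(setNames(as.list(rep(1, 26)),
                                featureNames(sch, with_ratios = FALSE)))
  row$AIA <- 21
  row$AA <- 42
  out <- computeRatios(row, sch)
  expect_equal(out$AIA_AA, 0.5)
  row$AmideII <- 0
  expect_warning(out2 <- computeRatios(row, sch), "denominator")
  expect_true(is.na(out2$AmideI_AmideII))
})

test_that("worked ratio arithmetic reproduces published group values", {
  sch <- defaultAlfalfaScheme()
  base <- as.data.frame(setNames(as.list(rep(1, 26)),
                                 featureNames(sch, with_ratios = FALSE)))
  wt <- base; wt$AIA <- 33.168; wt$AA <- 49.183; wt$AIIA <- 16.016
  wt <- computeRatios(wt, sch)
  expect_equal(round(wt$AIA_AA, 3), 0.674)
  expect_equal(round(wt$AIA_AIIA, 3), 2.071, tolerance = 1e-3)

  hb <- base; hb$alpha_helix <- 0.333; hb$beta_sheet <- 0.386
  hb <- computeRatios(hb, sch)
  expect_equal(round(hb$alpha_helix_beta_sheet, 3), 0.863)
})

test_that("extractFeatures produces one deterministic row per spectrum", {
  d <- defaultDesign()
  d@genotypes <- data.frame(genotype = "WT", n_samples = 1L)
  d@multipliers <- d@multipliers["WT", , drop = FALSE]
  d@subsamples <- 2L
  d@sample_sd <- 0; d@noise_sd <- 0; d@drift_sd <- c(0, 0, 0)
  set <- simulateSpectra(d, seed = 1)
  ft <- extractFeatures(set)
  expect_equal(nrow(ft), 2L)
  expect_equal(ncol(ft), 3L + 30L)  # design labels + 18+6+2+4 features
  # identical spectra give identical rows
  expect_equal(unlist(ft[1L, -(1:3)]), unlist(ft[2L, -(1:3)]))
  expect_identical(names(ft)[-(1:3)], featureNames(defaultAlfalfaScheme()))
})

test_that("extractFeatures recovers a planted STC3 amplitude ratio", {
  d <- defaultDesign()
  d@genotypes <- data.frame(genotype = c("WT", "HB12i"),
                            n_samples = c(2L, 2L))
  d@multipliers <- d@multipliers[c("WT", "HB12i"), , drop = FALSE]
  d@subsamples <- 2L
  d@sample_sd <- 0.002; d@noise_sd <- 5e-4; d@drift_sd <- c(0, 0, 0)
  set <- simulateSpectra(d, seed = 9)
  ft <- extractFeatures(set, normalize = "none")
  ratio <- mean(ft$STC3[ft$genotype == "HB12i"]) /
    mean(ft$STC3[ft$genotype == "WT"])
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 1.5)
})

test_that("one failing spectrum yields an NA row, not an abort", {
  grid <- seq(700, 4000, by = 2)
  good <- IRSpectrum(grid, gauss(grid, 1650, 12, 0.5) + 0.01,
                     "WT", "W1", "1")
  flat <- IRSpectrum(grid, rep(0.2, length(grid)), "WT", "W1", "2")
  set <- IRSpectrumSet(list(good, flat))
  expect_warning(ft <- extractFeatures(set), "W1/2")
  expect_false(anyNA(ft[1L, "AmideI"]))
  expect_true(is.na(ft[2L, "AmideI"]))
})
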