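# Region-wise HCA (Ward on squared Euclidean) and PCA of spectra.

test_that("per-sample mean spectra average subsamples within a region", {
  grid <- seq(1000, 1010, by = 2)
  mk <- function(vals, sid, sub) IRSpectrum(grid, vals, "WT", sid, sub)
  set <- IRSpectrumSet(list(
    mk(c(0, 1, 0, 1, 0, 1), "W1", "1"), mk(c(1, 0, 1, 0, 1, 0), "W1", "2"),
    mk(rep(0.3, 6), "W2", "1"), mk(rep(0.3, 6), "W2", "2")
  ))
  m <- meanSpectraPerSample(set)
  expect_equal(dim(m), c(2L, 6L))
  expect_equal(unname(m["W1", ]), rep(0.5, 6))
  expect_equal(unname(m["W2", ]), rep(0.3, 6))

  m2 <- meanSpectraPerSample(set, c(1006, 1002))
  expect_equal(colnames(m2), c("1002", "1004", "1006"))
  expect_error(meanSpectraPerSample(set, c(2000, 1500)), "outside")
})

test_that("Ward merge heights match the hand-computed criterion", {
  # 1-D points 0, 1, 10: first merge {0,1} at squared distance 1; the
  # Lance-Williams ward.D update then gives
  # d({0,1},{10}) = (2*100 + 2*81 - 1)/3 = 361/3
  mat <- matrix(c(0, 1, 10), ncol = 1,
                dimnames = list(c("a", "b", "c"), NULL))
  h <- hcaSpectra(mat)
  expect_equal(h$height, c(1, 361 / 3), tolerance = 1e-12)

  # duplicated rows merge first at height zero
  mat2 <- matrix(c(0, 0, 5, 1, 1, 2), nrow = 3,
                 dimnames = list(c("a", "b", "c"), NULL))
  h2 <- hcaSpectra(mat2)
  expect_equal(min(h2$height), 0)
  mat3 <- mat2
  rownames(mat3) <- c("a", "a", "c")
  expect_error(hcaSpectra(mat3), "unique")
})

test_that("HCA is row-order invariant with monotone heights", {
  set.seed(6)
  mat <- matrix(rnorm(80), nrow = 8,
                dimnames = list(paste0("s", 1:8), NULL))
  h1 <- hcaSpectra(mat)
  perm <- sample(8)
  h2 <- hcaSpectra(mat[perm, ])
  expect_equal(sort(h1$height), sort(h2$height), tolerance = 1e-10)
  expect_true(all(diff(h1$height) >= -1e-12))
  ct1 <- cutree(h1, 3)
  ct2 <- cutree(h2, 3)[names(ct1)]
  expect_equal(length(unique(paste(ct1, ct2))), 3L)  # same partition
})

test_that("two planted clusters separate at the last merge", {
  set.seed(10)
  grid <- seq(941, 1178, 2)
  mk <- function(center, sid) {
    a <- gauss(grid, center, 12, 0.5) + rnorm(length(grid), 0, 0.005)
    IRSpectrum(grid, a, "G", sid, "1")
  }
  set <- IRSpectrumSet(c(lapply(1:4, function(i) mk(1030, paste0("A", i))),
                         lapply(1:4, function(i) mk(1060, paste0("B", i)))))
  h <- hcaSpectra(meanSpectraPerSample(set))
  ct <- cutree(h, 2)
  expect_equal(unname(ct), rep(1:2, each = 4))
})

test_that("PCA agrees with eigendecomposition of the correlation matrix", {
  set.seed(12)
  mat <- matrix(rnorm(48), nrow = 6, ncol = 8,
                dimnames = list(NULL, format(seq(1000, 1014, 2))))
  p <- pcaSpectra(mat)
  ev <- eigen(cor(mat), symmetric = TRUE)
  k <- min(nrow(mat) - 1L, ncol(mat))
  expect_lt(max(abs(p$explained[1:k] -
                      (ev$values / sum(ev$values))[1:k])), 1e-8)
  for (j in 1:k) {
    dot <- abs(sum(p$loadings[, j] * ev$vectors[, j]))
    expect_equal(dot, 1, tolerance = 1e-8)  # equal up to column sign
  }
  expect_equal(sum(p$explained), 1, tolerance = 1e-9)
})

test_that("PCA basics: two observations, score geometry, sign convention", {
  m2 <- matrix(rnorm(10), nrow = 2,
               dimnames = list(NULL, format(1:5)))
  p2 <- pcaSpectra(m2)
  expect_equal(p2$explained[1], 1)

  set.seed(14)
  mat <- matrix(rnorm(60), nrow = 10, ncol = 6,
                dimnames = list(NULL, format(1:6)))
  p <- pcaSpectra(mat)
  expect_equal(unname(colMeans(p$scores)), rep(0, ncol(p$scores)),
               tolerance = 1e-10)
  cv <- crossprod(p$scores) / (nrow(mat) - 1)
  expect_equal(unname(diag(cv)), p$sdev^2, tolerance = 1e-10)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
  # largest-magnitude loading positive, deterministically
  for (j in seq_along(p$sdev)) {
    l <- p$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  p_again <- pcaSpectra(mat)
  expect_identical(p$loadings, p_again$loadings)

  expect_error(pcaSpectra(mat[1, , drop = FALSE]), "two observations")
  mat0 <- cbind(mat, `7` = 0)
  expect_warning(p0 <- pcaSpectra(mat0), "zero-variance")
  expect_equal(p0$dropped, "7")
})

test_that("loading profiles export in wavenumber order and round-trip", {
  set.seed(15)
  mat <- matrix(rnorm(40), nrow = 5,
                dimnames = list(NULL, format(seq(1014, 1000, -2))))
  p <- pcaSpectra(mat)
  lp <- loadingProfile(p, 1)
  expect_equal(lp$wavenumber, seq(1000, 1014, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(lp, f, row.names = FALSE)
  back <- read.csv(f)
  expect_equal(back$loading, lp$loading, tolerance = 1e-12)
  expect_error(loadingProfile(p, 99), "out of range")
})

test_that("a band moving against the rest loads PC1 with opposite sign", {
  # emulate the carbohydrate finding: one band near 1020 rises in WT
  # while the other bands rise in the transgenics -> its PC1 loading has
  # the opposite sign from the bulk of the region
  set.seed(16)
  grid <- seq(941, 1178, 2)
  mk <- function(gain1020, gain_rest, sid, sub) {
    a <- gauss(grid, 1020, 10, 0.5 * gain1020) +
      gauss(grid, 1080, 12, 0.4 * gain_rest) +
      gauss(grid, 1120, 12, 0.3 * gain_rest) +
      rnorm(length(grid), 0, 0.003)
    IRSpectrum(grid, a, if (gain1020 > 1) "WT" else "TG", sid, sub)
  }
  spectra <- c(
    lapply(1:8, function(i) mk(1.15, 1.00, paste0("W", (i + 1) %/% 2),
                               as.character(i %% 2 + 1))),
    lapply(1:8, function(i) mk(1.00, 1.15, paste0("T", (i + 1) %/% 2),
                               as.character(i %% 2 + 1)))
  )
  p <- pcaSpectra(t(regionMatrix(IRSpectrumSet(spectra))))
  lp <- loadingProfile(p, 1)
  at1020 <- lp$loading[which.min(abs(lp$wavenumber - 1020))]
  at1080 <- lp$loading[which.min(abs(lp$wavenumber - 1080))]
  at1120 <- lp$loading[which.min(abs(lp$wavenumber - 1120))]
  expect_lt(at1020 * at1080, 0)
  expect_gt(at1080 * at1120, 0)
})
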