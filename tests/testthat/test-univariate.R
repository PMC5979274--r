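# Nested mixed-model statistics: outlier screening, REML F tests,
# Tukey-Kramer letters, the wild-type contrast, and the subset rerun.

test_that("outlier screening is a no-op on clean or degenerate data", {
  set.seed(21)
  ft <- nestedTable(list(WT = 1, HB12i = 1.1, TT8i = 0.9), paperN)
  # zero-noise data: nothing can be an outlier
  ft0 <- ft
  ft0$y <- ave(ft0$y, ft0$genotype, FUN = function(x) x[1])
  out0 <- removeOutliers(ft0, "y")
  expect_equal(nrow(out0$removed), 0L)
  # infinite threshold disables screening entirely
  outI <- removeOutliers(ft, "y", threshold = Inf)
  expect_identical(outI$table, ft)
  expect_error(removeOutliers(ft, "nope"), "unknown feature")
})

test_that("a planted gross outlier is the one observation removed", {
  set.seed(41)
  ft <- nestedTable(list(WT = 1, HB12i = 1.1, TT8i = 0.9), paperN,
                    sigma_s = 0.01, sigma_e = 0.005)
  stopifnot(nrow(ft) == 100L)
  clean <- removeOutliers(ft, "y")
  expect_equal(nrow(clean$removed), 0L)  # seed chosen with a quiet null
  i <- 37L
  ft$y[i] <- ft$y[i] + 10 * 0.005
  out <- removeOutliers(ft, "y")
  expect_equal(nrow(out$removed), 1L)
  expect_equal(out$removed$sample_id, ft$sample_id[i])
  expect_equal(out$removed$subsample_id, ft$subsample_id[i])
  expect_true(is.na(out$table$y[i]))
  expect_equal(sum(is.na(out$table$y)), 1L)
})

test_that("degenerate designs are flagged, not fitted", {
  ft <- data.frame(genotype = c("WT", "TT8i"), sample_id = c("W1", "T1"),
                   subsample_id = c("1", "1"), y = c(1, 2),
                   stringsAsFactors = FALSE)
  fit <- fitFeature(ft, "y")
  expect_true(fit$degenerate)
  expect_true(is.na(fit$p))
  set.seed(1)
  one_geno <- nestedTable(list(WT = 1), c(WT = 4))
  expect_true(fitFeature(one_geno, "y")$degenerate)
})

test_that("letter groups partition exactly by adjusted p at alpha", {
  set.seed(5)
  for (i in 1:6) {
    ft <- nestedTable(list(WT = 0.164, HB12i = runif(1, 0.16, 0.23),
                           TT8i = runif(1, 0.16, 0.23)), paperN,
                      sigma_s = 0.008, sigma_e = 0.004)
    fit <- fitFeature(ft, "y")
    expect_false(fit$degenerate)
    letts <- setNames(fit$means$letters, fit$means$genotype)
    for (r in seq_len(nrow(fit$pairs))) {
      gg <- strsplit(fit$pairs$contrast[r], " - ")[[1]]
      shares <- length(intersect(strsplit(letts[[gg[1]]], "")[[1]],
                                 strsplit(letts[[gg[2]]], "")[[1]])) > 0
      expect_identical(shares, fit$pairs$p.value[r] >= 0.05)
    }
  }
})

test_that("balanced-design REML F equals one-way ANOVA on sample means", {
  set.seed(8)
  ft <- nestedTable(list(A = 1, B = 1.02, C = 0.99),
                    c(A = 4, B = 4, C = 4), subsamples = 5,
                    sigma_s = 0.02, sigma_e = 0.005)
  res <- nestedFTest(ft, "y")
  sm <- aggregate(y ~ genotype + sample_id, ft, mean)
  a <- anova(aov(y ~ genotype, sm))
  expect_lt(abs(res$F - a$`F value`[1]) / a$`F value`[1], 1e-6)
  expect_lt(abs(res$p - a$`Pr(>F)`[1]), 1e-6)
  expect_lt(abs(res$den_df - a$Df[2]), 1e-4)
})

test_that("permuting genotype labels gives uniform F-test p-values", {
  set.seed(13)
  ft <- nestedTable(list(WT = 0.164, HB12i = 0.23, TT8i = 0.187), paperN,
                    sigma_s = 0.007, sigma_e = 0.0035)
  samples <- unique(ft[, c("genotype", "sample_id")])
  pvals <- replicate(500, {
    perm <- setNames(sample(samples$genotype), samples$sample_id)
    ftp <- ft
    ftp$genotype <- perm[ftp$sample_id]
    nestedFTest(ftp, "y")$p
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("published STC3 effect pattern separates all three letter groups", {
  # group means and n from the source study's STC3 row, noise at the
  # printed-SEM scale
  set.seed(17)
  hits <- replicate(30, {
    ft <- nestedTable(list(WT = 0.164, HB12i = 0.23, TT8i = 0.187), paperN,
                      sigma_s = 0.007, sigma_e = 0.0035)
    fit <- fitFeature(ft, "y")
    length(unique(fit$means$letters)) == 3L &&
      all(nchar(fit$means$letters) == 1L)
  })
  expect_gte(mean(hits), 0.8)
})

test_that("subsetRerun reproduces the full analysis when keeping all", {
  set.seed(2)
  ft <- nestedTable(list(WT = 0.164, HB12i = 0.23, TT8i = 0.187), paperN,
                    sigma_s = 0.007, sigma_e = 0.0035)
  full <- univariateAnalysis(ft, features = "y")
  sub <- subsetRerun(ft, unique(ft$sample_id), features = "y")
  expect_equal(sub$table, full$table)
  expect_error(subsetRerun(ft, c("S1", "S99"), features = "y"), "unknown")
  wt_only <- unique(ft$sample_id[ft$genotype == "WT"])
  expect_error(subsetRerun(ft, wt_only, features = "y"), "two genotypes")
})
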