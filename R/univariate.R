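## Nested mixed-model univariate statistics: per feature,
##   Y_ijk = mu + geno_i + sample(geno)_ij + e_ijk
## fit by REML with Satterthwaite denominator degrees of freedom,
## Tukey-Kramer multiple comparison, wild-type-vs-transgenic contrast,
## studentized-residual outlier screening and a residual normality check.

.modelFrame <- function(ft, feature, wt_label = NULL) {
  if (!feature %in% names(ft)) stop("unknown feature: ", feature)
  d <- data.frame(
    y = ft[[feature]],
    genotype = as.character(ft$genotype),
    sample_id = as.character(ft$sample_id),
    subsample_id = as.character(ft$subsample_id),
    stringsAsFactors = FALSE
  )
  d <- d[!is.na(d$y), , drop = FALSE]
  lev <- unique(d$genotype)
  if (!is.null(wt_label) && wt_label %in% lev)
    lev <- c(wt_label, setdiff(lev, wt_label))
  d$genotype <- factor(d$genotype, levels = lev)
  d$sample_id <- factor(d$sample_id)
  d
}

## REML fit of the nested model; NULL when the design cannot support it
.fitNested <- function(d) {
  if (nlevels(d$genotype) < 2L) return(NULL)
  if (nlevels(d$sample_id) >= nrow(d)) return(NULL)  # no residual replication
  if (sd(d$y) == 0) return(NULL)
  tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(y ~ genotype + (1 | sample_id), data = d,
                     control = lme4::lmerControl(check.conv.singular =
                       lme4::.makeCC(action = "ignore", tol = 1e-4)))
    )),
    error = function(e) NULL
  )
}

## externally studentized (leave-one-out form) conditional residuals
.studentized <- function(m) {
  e <- resid(m)
  h <- pmin(stats::hatvalues(m), 1 - 1e-10)
  s <- stats::sigma(m)
  if (!is.finite(s) || s <= 1e-12) return(rep(0, length(e)))
  r <- e / (s * sqrt(1 - h))
  nu <- stats::df.residual(m)
  r2 <- pmin(r^2, nu - 1e-8)
  r * sqrt((nu - 1) / (nu - r2))
}

#' Screen outlier observations with studentized residuals
#'
#' Fits the nested model once for the given feature and removes, in a
#' single pass, every observation whose externally studentized conditional
#' residual exceeds the threshold in absolute value (default 2.5). When the
#' design cannot support the model (fewer than two genotypes, no subsample
#' replication, constant response) nothing is removed.
#'
#' @param ft feature table from [extractFeatures()].
#' @param feature feature (column) name.
#' @param threshold absolute studentized-residual cutoff (default 2.5;
#'   `Inf` disables screening).
#' @param wt_label reference genotype label (affects only factor ordering).
#' @return list with `table` (filtered feature table) and `removed`
#'   (data.frame of removed observations with their residuals).
#' @export
removeOutliers <- function(ft, feature, threshold = 2.5, wt_label = "WT") {
  d <- .modelFrame(ft, feature, wt_label)
  empty <- data.frame(genotype = character(), sample_id = character(),
                      subsample_id = character(), value = numeric(),
                      studentized = numeric(), stringsAsFactors = FALSE)
  if (!is.finite(threshold))
    return(list(table = ft, removed = empty))
  m <- .fitNested(d)
  if (is.null(m)) return(list(table = ft, removed = empty))
  t_i <- .studentized(m)
  out <- which(abs(t_i) > threshold)
  if (!length(out)) return(list(table = ft, removed = empty))
  removed <- data.frame(
    genotype = d$genotype[out], sample_id = as.character(d$sample_id[out]),
    subsample_id = d$subsample_id[out], value = d$y[out],
    studentized = t_i[out], stringsAsFactors = FALSE
  )
  ## only the flagged observations' value for THIS feature is removed (set
  ## NA), so other features keep their full data
  key <- paste(ft$genotype, ft$sample_id, ft$subsample_id)
  drop_key <- paste(removed$genotype, removed$sample_id, removed$subsample_id)
  ft2 <- ft
  ft2[[feature]][key %in% drop_key] <- NA_real_
  list(table = ft2, removed = removed)
}

## compact letter display from a logical "significantly different" matrix;
## groups must be ordered by decreasing mean. Insert-and-absorb: start from
## one letter containing everything, split on each significant pair, drop
## columns that became subsets of another. Two groups share a letter iff
## their difference is not significant.
.letterDisplay <- function(signif_mat) {
  k <- nrow(signif_mat)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      if (!signif_mat[i, j]) next
      newcols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          c1 <- col; c1[i] <- FALSE
          c2 <- col; c2[j] <- FALSE
          newcols <- c(newcols, list(c1, c2))
        } else {
          newcols <- c(newcols, list(col))
        }
      }
      ## absorb: drop any column that is a subset of another
      keep <- rep(TRUE, length(newcols))
      for (a in seq_along(newcols)) {
        for (b in seq_along(newcols)) {
          if (a == b || !keep[a]) next
          if (all(newcols[[a]] <= newcols[[b]]) &&
              !identical(newcols[[a]], newcols[[b]])) keep[a] <- FALSE
          if (identical(newcols[[a]], newcols[[b]]) && a > b) keep[a] <- FALSE
        }
      }
      cols <- newcols[keep]
    }
  }
  ## order letters by the best (highest-mean) member they contain
  ord <- order(vapply(cols, function(col) which(col)[1L], integer(1)))
  cols <- cols[ord]
  letts <- vapply(seq_len(k), function(g)
    paste(letters[which(vapply(cols, `[`, logical(1), g))], collapse = ""),
    character(1))
  letts
}

#' Overall genotype F test of the nested model
#'
#' Fast path computing only the REML fit and its Satterthwaite F test —
#' what simulation loops (type-I error, permutation nulls, power checks)
#' need, without least-squares means, letters or contrasts.
#'
#' @inheritParams fitFeature
#' @return list with `F`, `p`, `num_df`, `den_df`, `degenerate`.
#' @export
nestedFTest <- function(ft, feature, wt_label = "WT") {
  d <- .modelFrame(ft, feature, wt_label)
  m <- .fitNested(d)
  if (is.null(m))
    return(list(F = NA_real_, p = NA_real_, num_df = NA_real_,
                den_df = NA_real_, degenerate = TRUE))
  an <- tryCatch(anova(m, ddf = "Satterthwaite"), error = function(e) NULL)
  if (is.null(an) || !nrow(an))
    return(list(F = NA_real_, p = NA_real_, num_df = NA_real_,
                den_df = NA_real_, degenerate = TRUE))
  list(F = an$`F value`[1L], p = an$`Pr(>F)`[1L], num_df = an$NumDF[1L],
       den_df = an$DenDF[1L], degenerate = FALSE)
}

#' Fit the nested model for one feature
#'
#' REML fit of `Y_ijk = mu + genotype_i + sample(genotype)_ij + e_ijk` with
#' Satterthwaite denominator degrees of freedom, genotype least-squares
#' means and their standard errors, the overall genotype F test,
#' Tukey-Kramer all-pairs comparisons (valid for unequal group sizes) with
#' letter groups, the one-degree wild-type-versus-pooled-transgenic
#' contrast, and a Shapiro-Wilk check on conditional residuals. The
#' reported `sem` is the largest least-squares-mean standard error (the
#' single SEM convention of unbalanced-design summary tables).
#'
#' @param ft feature table (typically already outlier-screened).
#' @param feature feature name.
#' @param wt_label wild-type genotype label used for the contrast.
#' @param alpha significance level for the letter display (default 0.05).
#' @return list of class `featureFit`: `feature`, `degenerate`, `n`,
#'   `means` (data.frame genotype/emmean/SE/df/letters), `sem`, `F`, `p`,
#'   `pairs` (Tukey-Kramer summary), `contrast_estimate`, `contrast_p`,
#'   `shapiro_p`, and the fitted `model`.
#' @export
fitFeature <- function(ft, feature, wt_label = "WT", alpha = 0.05) {
  d <- .modelFrame(ft, feature, wt_label)
  res <- list(feature = feature, degenerate = TRUE, n = nrow(d),
              means = NULL, sem = NA_real_, F = NA_real_, p = NA_real_,
              pairs = NULL, contrast_estimate = NA_real_,
              contrast_p = NA_real_, shapiro_p = NA_real_, model = NULL)
  class(res) <- "featureFit"
  m <- .fitNested(d)
  if (is.null(m)) return(res)
  an <- tryCatch(anova(m, ddf = "Satterthwaite"), error = function(e) NULL)
  if (is.null(an) || !nrow(an)) return(res)
  em <- emmeans::emmeans(m, "genotype", lmer.df = "satterthwaite")
  ems <- as.data.frame(summary(em))
  pr <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise"),
                              adjust = "tukey"))
  k <- nrow(ems)
  ## significance matrix in decreasing-mean order for the letter display
  ord <- order(-ems$emmean)
  sig <- matrix(FALSE, k, k)
  glev <- as.character(ems$genotype)
  for (r in seq_len(nrow(pr))) {
    gg <- strsplit(pr$contrast[r], " - ")[[1L]]
    gg <- gsub("^\\(|\\)$", "", gg)
    i <- match(gg[1L], glev)
    j <- match(gg[2L], glev)
    sig[i, j] <- sig[j, i] <- pr$p.value[r] < alpha
  }
  letts <- .letterDisplay(sig[ord, ord, drop = FALSE])[order(ord)]
  means <- data.frame(genotype = glev, emmean = ems$emmean, SE = ems$SE,
                      df = ems$df, letters = letts,
                      stringsAsFactors = FALSE)
  res$degenerate <- FALSE
  res$means <- means
  res$sem <- max(ems$SE)
  res$F <- an$`F value`[1L]
  res$p <- an$`Pr(>F)`[1L]
  res$pairs <- pr
  if (wt_label %in% glev && k >= 2L) {
    cf <- ifelse(glev == wt_label, 1, -1 / (k - 1))
    ct <- as.data.frame(summary(emmeans::contrast(
      em, method = list(WT_vs_transgenic = cf))))
    res$contrast_estimate <- ct$estimate[1L]
    res$contrast_p <- ct$p.value[1L]
  }
  res$shapiro_p <- tryCatch(shapiro.test(resid(m))$p.value,
                            error = function(e) NA_real_)
  res$model <- m
  res
}

#' @export
print.featureFit <- function(x, ...) {
  cat(sprintf("featureFit: %s (n = %d)\n", x$feature, x$n))
  if (x$degenerate) {
    cat("  degenerate design: no model fitted\n")
    return(invisible(x))
  }
  print(x$means, row.names = FALSE)
  cat(sprintf("  F = %.3f, p = %.4g; WT-vs-transgenic p = %.4g; SEM = %.4g\n",
              x$F, x$p, x$contrast_p, x$sem))
  invisible(x)
}

#' Univariate analysis of every feature
#'
#' Per feature: single-pass studentized-residual outlier screening (see
#' [removeOutliers()]), then the nested-model fit of [fitFeature()]. The
#' result mirrors a means-with-letters summary table: genotype
#' least-squares means, letter groups, SEM, overall F-test p,
#' wild-type-vs-transgenic contrast p, residual-normality p and the number
#' of observations removed.
#'
#' @param ft feature table from [extractFeatures()].
#' @param features feature names (default: every numeric column).
#' @param wt_label wild-type genotype label.
#' @param alpha significance level for letters.
#' @param outlier_threshold studentized-residual cutoff (default 2.5).
#' @return list of class `univariateResult`: `table` (the summary
#'   data.frame), `fits` (per-feature `featureFit`s) and `removed`
#'   (per-feature removed observations).
#' @export
univariateAnalysis <- function(ft, features = NULL, wt_label = "WT",
                               alpha = 0.05, outlier_threshold = 2.5) {
  if (is.null(features)) {
    num <- vapply(ft, is.numeric, logical(1))
    features <- setdiff(names(ft)[num], c("genotype", "sample_id",
                                          "subsample_id"))
  }
  glev <- unique(as.character(ft$genotype))
  if (wt_label %in% glev) glev <- c(wt_label, setdiff(glev, wt_label))
  fits <- list()
  removed <- list()
  rows <- list()
  for (f in features) {
    scr <- removeOutliers(ft, f, threshold = outlier_threshold,
                          wt_label = wt_label)
    fit <- fitFeature(scr$table, f, wt_label = wt_label, alpha = alpha)
    fits[[f]] <- fit
    removed[[f]] <- scr$removed
    row <- list(feature = f)
    for (g in glev) {
      if (!fit$degenerate && g %in% fit$means$genotype) {
        i <- match(g, fit$means$genotype)
        row[[paste0("mean_", g)]] <- fit$means$emmean[i]
        row[[paste0("letters_", g)]] <- fit$means$letters[i]
      } else {
        row[[paste0("mean_", g)]] <- NA_real_
        row[[paste0("letters_", g)]] <- NA_character_
      }
    }
    row$SEM <- fit$sem
    row$p <- fit$p
    row$contrast_p <- fit$contrast_p
    row$shapiro_p <- fit$shapiro_p
    row$n_removed <- nrow(scr$removed)
    row$degenerate <- fit$degenerate
    rows[[f]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
              fits = fits, removed = removed)
  class(out) <- "univariateResult"
  out
}

#' @export
print.univariateResult <- function(x, ...) {
  cat("univariateResult:", nrow(x$table), "features\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Re-run the univariate analysis on a sample subset
#'
#' Repeats the full screening-and-fitting pipeline keeping only the listed
#' sample ids — e.g. two replicates per genotype, to examine how much of
#' the significance structure survives at a pilot-study population size.
#'
#' @param ft feature table.
#' @param keep character vector of sample ids to keep.
#' @inheritParams univariateAnalysis
#' @return A `univariateResult`, as from [univariateAnalysis()].
#' @export
subsetRerun <- function(ft, keep, features = NULL, wt_label = "WT",
                        alpha = 0.05, outlier_threshold = 2.5) {
  missing_ids <- setdiff(keep, unique(ft$sample_id))
  if (length(missing_ids))
    stop("unknown sample ids: ", paste(missing_ids, collapse = ", "))
  sub <- ft[ft$sample_id %in% keep, , drop = FALSE]
  if (!nrow(sub)) stop("empty subset")
  if (length(unique(sub$genotype)) < 2L)
    stop("subset must retain at least two genotypes")
  univariateAnalysis(sub, features = features, wt_label = wt_label,
                     alpha = alpha, outlier_threshold = outlier_threshold)
}
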