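#' Per-sample mean spectra restricted to a region
#'
#' Averages the subsample spectra of each biological sample (arithmetic
#' mean) and restricts the result to the region's wavenumber window, the
#' input used for hierarchical clustering so dendrogram leaves are samples.
#'
#' @param set an [IRSpectrumSet-class].
#' @param region `c(high, low)` in cm^-1 or a row of [schemeRegions()];
#'   `NULL` keeps the full grid.
#' @return numeric matrix, samples x wavenumbers, rownames = sample ids,
#'   colnames = wavenumbers.
#' @export
meanSpectraPerSample <- function(set, region = NULL) {
  m <- t(regionMatrix(set, region))
  sid <- sampleId(set)
  out <- rowsum(m, group = sid, reorder = FALSE) /
    as.vector(table(factor(sid, levels = unique(sid))))
  out
}

#' Region-restricted spectra matrix
#'
#' @param set an [IRSpectrumSet-class].
#' @param region as in [meanSpectraPerSample()].
#' @return numeric matrix wavenumbers x spectra (one column per subsample
#'   spectrum).
#' @export
regionMatrix <- function(set, region = NULL) {
  stopifnot(is(set, "IRSpectrumSet"))
  mat <- absorbance(set)
  w <- wavenumbers(set)
  if (!is.null(region)) {
    b <- .regionBounds(region)
    if (b["low"] < min(w) - 1e-9 || b["high"] > max(w) + 1e-9)
      stop(sprintf("region %.0f-%.0f cm-1 outside the grid (%.1f-%.1f)",
                   b["high"], b["low"], min(w), max(w)))
    keep <- which(w >= b["low"] - 1e-9 & w <= b["high"] + 1e-9)
    mat <- mat[keep, , drop = FALSE]
    w <- w[keep]
  }
  rownames(mat) <- format(w, trim = TRUE)
  mat
}

#' Hierarchical clustering of spectra (Ward on squared Euclidean)
#'
#' Pairwise Euclidean distances between rows are squared and fed to
#' `hclust(method = "ward.D")`, i.e. the classic Ward recipe with the
#' non-square-rooted Lance-Williams update, so merge heights are on the
#' squared-distance scale. Heights are monotone non-decreasing and the
#' tree is invariant to row order (up to leaf ordering).
#'
#' @param mat numeric matrix, observations (samples) x wavenumbers, with
#'   unique rownames.
#' @return An `hclust` tree with leaf labels = rownames.
#' @export
hcaSpectra <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("rows must carry unique sample ids")
  hclust(dist(mat, method = "euclidean")^2, method = "ward.D")
}

#' Export a dendrogram as Newick plus a merge table
#'
#' @param tree an `hclust` from [hcaSpectra()].
#' @param prefix output path prefix; writes `<prefix>.nwk` and
#'   `<prefix>_merges.csv` (merge indices with heights; negative entries
#'   are leaves, positive entries earlier merges).
#' @return invisibly, the two file paths.
#' @export
exportDendrogram <- function(tree, prefix) {
  stopifnot(inherits(tree, "hclust"))
  nwk <- paste0(prefix, ".nwk")
  ape::write.tree(ape::as.phylo(tree), file = nwk)
  merges <- data.frame(a = tree$merge[, 1L], b = tree$merge[, 2L],
                       height = tree$height)
  mcsv <- paste0(prefix, "_merges.csv")
  write.csv(merges, mcsv, row.names = FALSE)
  invisible(c(newick = nwk, merges = mcsv))
}

#' Principal component analysis of region spectra
#'
#' Centers and scales every wavenumber column to unit variance, then a
#' singular value decomposition (via `prcomp`). Zero-variance columns
#' cannot be scaled and are dropped with a warning rather than aborting a
#' batch. Component signs are fixed deterministically: each loading column
#' is flipped so its largest-magnitude entry is positive.
#'
#' @param mat numeric matrix, observations x wavenumbers.
#' @return list of class `irpca`: `scores` (observations x components),
#'   `loadings` (wavenumbers x components, orthonormal columns),
#'   `explained` (proportions summing to 1 over all components), `sdev`,
#'   `center`, `scale`, `dropped` (names of dropped constant columns).
#' @export
pcaSpectra <- function(mat) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 2L) stop("PCA needs at least two observations")
  v <- apply(mat, 2L, var)
  dropped <- colnames(mat)[v <= 0]
  if (length(dropped)) {
    warning(length(dropped), " zero-variance wavenumber column(s) dropped")
    mat <- mat[, v > 0, drop = FALSE]
  }
  p <- prcomp(mat, center = TRUE, scale. = TRUE)
  flip <- apply(p$rotation, 2L, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2L, flip, `*`)
  loadings <- sweep(p$rotation, 2L, flip, `*`)
  expl <- p$sdev^2 / sum(p$sdev^2)
  structure(
    list(scores = scores, loadings = loadings, explained = expl,
         sdev = p$sdev, center = p$center, scale = p$scale,
         dropped = dropped),
    class = "irpca"
  )
}

#' @export
print.irpca <- function(x, ...) {
  cat(sprintf("irpca: %d observations, %d variables\n",
              nrow(x$scores), nrow(x$loadings)))
  k <- min(3L, length(x$explained))
  cat("  explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$explained[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Loading-versus-wavenumber profile of one component
#'
#' @param p an `irpca` from [pcaSpectra()].
#' @param component component index.
#' @return data.frame `wavenumber`, `loading` in ascending wavenumber
#'   order, ready for plotting or CSV export.
#' @export
loadingProfile <- function(p, component = 1L) {
  stopifnot(inherits(p, "irpca"))
  if (component < 1L || component > ncol(p$loadings))
    stop("component index out of range")
  w <- as.numeric(rownames(p$loadings))
  if (any(is.na(w)))
    stop("loadings lack numeric wavenumber rownames")
  o <- order(w)
  data.frame(wavenumber = w[o], loading = p$loadings[o, component])
}

#' Region-wise ordination of a spectrum set
#'
#' Convenience wrapper running HCA (on per-sample mean spectra, as is
#' conventional for readable dendrograms) and PCA (on all subsample
#' spectra by default, or on sample means) for one region.
#'
#' @param set an [IRSpectrumSet-class] (normalize first for comparability
#'   across samples).
#' @param region as in [meanSpectraPerSample()].
#' @param pca_observations `"subsample"` (default) or `"sample_mean"`.
#' @return list with `hca` (hclust), `pca` (`irpca`), and the matrices
#'   used.
#' @export
ordinateRegion <- function(set, region = NULL,
                           pca_observations = c("subsample", "sample_mean")) {
  pca_observations <- match.arg(pca_observations)
  means <- meanSpectraPerSample(set, region)
  pmat <- if (pca_observations == "subsample") {
    m <- t(regionMatrix(set, region))
    rownames(m) <- paste(sampleId(set), subsampleId(set), sep = ".")
    m
  } else {
    means
  }
  list(hca = hcaSpectra(means), pca = pcaSpectra(pmat),
       hca_matrix = means, pca_matrix = pmat)
}
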