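#' Replication harness: planted-effect recovery across seeds
#'
#' Runs the full pipeline on freshly simulated data for each seed and
#' summarises how well the analysis stages re-detect the design's planted
#' structure: per planted band effect, whether the genotype's fitted
#' least-squares mean moved in the planted direction relative to the
#' reference genotype; the overall F-test p of each planted band at the
#' full sample size and after restriction to two samples per genotype
#' (the pilot-population rerun); and whether, in the carbohydrate (CHO)
#' region of the normalized spectra, hierarchical clustering isolates the
#' reference genotype in its own top-level branch and PC1 separates its
#' scores from all transgenic scores without overlap.
#'
#' @param seeds integer vector of simulation seeds.
#' @param design a [SyntheticDesign-class] (default [defaultDesign()]).
#' @param keep_subset sample ids for the small-population rerun (default:
#'   the second and third sample of every genotype).
#' @param wt_label reference genotype.
#' @param region_name region used for the ordination check.
#' @param alpha significance level.
#' @return list with `directions` (data.frame band, genotype, direction,
#'   rate, n_seeds), `significance` (data.frame seed, band, p_full,
#'   p_subset), `ordination` (data.frame seed, wt_isolated — reference
#'   genotype alone at the 2-cluster cut, wt_own_cluster_k3 — alone at
#'   the 3-cluster cut, pc1_separated), and the per-seed detail.
#' @export
recoveryStudy <- function(seeds = 1:20, design = defaultDesign(),
                          keep_subset = NULL, wt_label = "WT",
                          region_name = "CHO", alpha = 0.05) {
  pd <- plantedDirections()
  bands <- unique(pd$band)
  scheme <- defaultAlfalfaScheme()
  region <- getRegion(scheme, region_name)
  if (is.null(keep_subset)) {
    g <- design@genotypes$genotype
    pref <- toupper(substr(g, 1L, 1L))
    keep_subset <- as.vector(vapply(pref, function(p) paste0(p, 2:3),
                                    character(2)))
  }
  dir_rows <- list()
  sig_rows <- list()
  ord_rows <- list()
  for (sd_i in seeds) {
    set <- simulateSpectra(design, seed = sd_i)
    ft <- suppressWarnings(extractFeatures(set, scheme))
    uv <- suppressWarnings(
      univariateAnalysis(ft, features = bands, wt_label = wt_label))
    uv_sub <- suppressWarnings(
      subsetRerun(ft, keep_subset, features = bands, wt_label = wt_label))
    for (r in seq_len(nrow(pd))) {
      fit <- uv$fits[[pd$band[r]]]
      ok <- NA
      if (!fit$degenerate && wt_label %in% fit$means$genotype &&
          pd$genotype[r] %in% fit$means$genotype) {
        delta <- fit$means$emmean[match(pd$genotype[r],
                                        fit$means$genotype)] -
          fit$means$emmean[match(wt_label, fit$means$genotype)]
        ok <- sign(delta) == pd$direction[r]
      }
      dir_rows[[length(dir_rows) + 1L]] <- data.frame(
        seed = sd_i, band = pd$band[r], genotype = pd$genotype[r],
        direction = pd$direction[r], correct = ok)
    }
    for (b in bands) {
      sig_rows[[length(sig_rows) + 1L]] <- data.frame(
        seed = sd_i, band = b,
        p_full = uv$fits[[b]]$p, p_subset = uv_sub$fits[[b]]$p)
    }
    nset <- normalizeSet(set)
    ord <- suppressWarnings(ordinateRegion(nset, region))
    wt_samples <- unique(sampleId(set)[genotype(set) == wt_label])
    ct <- stats::cutree(ord$hca, k = 2L)
    iso <- setequal(names(ct)[ct == ct[[wt_samples[1L]]]], wt_samples)
    ct3 <- stats::cutree(ord$hca, k = 3L)
    own3 <- setequal(names(ct3)[ct3 == ct3[[wt_samples[1L]]]], wt_samples)
    sc <- ord$pca$scores[, 1L]
    is_wt <- genotype(set) == wt_label
    sep <- max(sc[is_wt]) < min(sc[!is_wt]) ||
      min(sc[is_wt]) > max(sc[!is_wt])
    ord_rows[[length(ord_rows) + 1L]] <- data.frame(
      seed = sd_i, wt_isolated = iso, wt_own_cluster_k3 = own3,
      pc1_separated = sep)
  }
  directions <- do.call(rbind, dir_rows)
  agg <- aggregate(correct ~ band + genotype + direction, directions,
                   function(x) mean(x, na.rm = TRUE))
  names(agg)[names(agg) == "correct"] <- "rate"
  agg$n_seeds <- length(seeds)
  list(
    directions = agg[order(agg$genotype, agg$band), ],
    directions_detail = directions,
    significance = do.call(rbind, sig_rows),
    ordination = do.call(rbind, ord_rows)
  )
}

#' Type-I error of the nested F test under the null
#'
#' Simulates the nested design (default: the study's 4/5/11 samples with 5
#' subsamples) with identical genotype means and equal sample and
#' subsample standard deviations, and returns the rejection rate of the
#' REML/Satterthwaite genotype F test at `alpha`.
#'
#' @param n_sim number of simulated datasets.
#' @param n_samples named integer vector of samples per genotype.
#' @param subsamples subsample count per sample.
#' @param sigma_s,sigma_e sample and subsample SDs.
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return observed rejection rate (numeric scalar).
#' @export
typeIErrorRate <- function(n_sim = 500, n_samples = c(WT = 4, HB12i = 11,
                                                      TT8i = 5),
                           subsamples = 5, sigma_s = 0.01,
                           sigma_e = 0.01, alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rej <- logical(n_sim)
  geno <- rep(names(n_samples), n_samples)
  sid <- paste0("S", seq_along(geno))
  for (i in seq_len(n_sim)) {
    b <- rnorm(length(sid), 0, sigma_s)
    ft <- data.frame(
      genotype = rep(geno, each = subsamples),
      sample_id = rep(sid, each = subsamples),
      subsample_id = as.character(rep(seq_len(subsamples),
                                      length(sid))),
      y = rep(b, each = subsamples) +
        rnorm(length(sid) * subsamples, 0, sigma_e),
      stringsAsFactors = FALSE
    )
    p <- nestedFTest(ft, "y")$p
    rej[i] <- !is.na(p) && p < alpha
  }
  mean(rej)
}
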