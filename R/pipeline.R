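#' Save / load a synthetic design as JSON
#'
#' @param design a [SyntheticDesign-class].
#' @param path JSON file path.
#' @return `saveDesign`: `path` invisibly; `loadDesign`: the design.
#' @export
saveDesign <- function(design, path) {
  stopifnot(is(design, "SyntheticDesign"))
  obj <- list(
    bands = design@bands,
    genotypes = design@genotypes,
    multipliers = as.data.frame(design@multipliers),
    subsamples = design@subsamples,
    sample_sd = design@sample_sd,
    noise_sd = design@noise_sd,
    drift_sd = design@drift_sd,
    grid = design@grid
  )
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname saveDesign
#' @export
loadDesign <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mult <- as.matrix(as.data.frame(obj$multipliers))
  rownames(mult) <- obj$genotypes$genotype
  new("SyntheticDesign",
    bands = as.data.frame(obj$bands),
    genotypes = data.frame(genotype = obj$genotypes$genotype,
                           n_samples = as.integer(obj$genotypes$n_samples),
                           stringsAsFactors = FALSE),
    multipliers = mult,
    subsamples = as.integer(obj$subsamples),
    sample_sd = as.numeric(obj$sample_sd),
    noise_sd = as.numeric(obj$noise_sd),
    drift_sd = as.numeric(obj$drift_sd),
    grid = as.numeric(obj$grid)
  )
}

#' Default pipeline configuration
#'
#' @param outdir artifact directory.
#' @param seed integer seed used for simulation (and recorded in the
#'   manifest).
#' @param spectra_dir directory of spectrum CSVs; `NULL` simulates from
#'   `design` instead.
#' @param design a [SyntheticDesign-class] used when simulating.
#' @param scheme a [RegionScheme-class].
#' @param regions region names to ordinate (default: all scheme regions).
#' @param normalize,window,polyorder preprocessing, see
#'   [extractFeatures()].
#' @param wt_label,alpha,outlier_threshold statistics, see
#'   [univariateAnalysis()].
#' @param keep_samples optional sample ids for an additional subset rerun.
#' @param pca_observations see [ordinateRegion()].
#' @return named list of configuration values for [runPipeline()].
#' @export
pipelineConfig <- function(outdir, seed = 1L, spectra_dir = NULL,
                           design = defaultDesign(),
                           scheme = defaultAlfalfaScheme(),
                           regions = NULL,
                           normalize = "minmax", window = 9L,
                           polyorder = 3L, wt_label = "WT", alpha = 0.05,
                           outlier_threshold = 2.5, keep_samples = NULL,
                           pca_observations = "subsample") {
  list(outdir = outdir, seed = as.integer(seed), spectra_dir = spectra_dir,
       design = design, scheme = scheme, regions = regions,
       normalize = normalize, window = as.integer(window),
       polyorder = as.integer(polyorder), wt_label = wt_label,
       alpha = alpha, outlier_threshold = outlier_threshold,
       keep_samples = keep_samples, pca_observations = pca_observations)
}

#' Run the whole profiling pipeline
#'
#' Chains the stages in analysis order: obtain spectra (simulate from the
#' design, or read `spectra_dir`), extract the feature table, run the
#' univariate nested-model analysis (plus an optional sample-subset
#' rerun), and ordinate every requested region with HCA and PCA. All
#' artifacts are written under `config$outdir`:
#' `features.csv`, `univariate.csv` (and `univariate_subset.csv`),
#' per-region `<region>.nwk`, `<region>_merges.csv`, `<region>_scores.csv`,
#' `<region>_loadings.csv`, `<region>_explained.csv`, and `manifest.json`
#' recording the configuration, seed and package version (no wall-clock
#' fields, so a rerun from the same manifest reproduces every output
#' byte-for-byte given identical floating-point behaviour).
#'
#' @param config list from [pipelineConfig()].
#' @return invisibly, a list with the feature table, the univariate
#'   result(s), the per-region ordinations and the artifact paths.
#' @export
runPipeline <- function(config) {
  cfg <- config
  if (is.null(cfg$outdir)) stop("config$outdir is required")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  scheme <- cfg$scheme
  if (is.null(scheme)) scheme <- defaultAlfalfaScheme()

  set <- if (!is.null(cfg$spectra_dir)) {
    if (!dir.exists(cfg$spectra_dir))
      stop("spectra directory not found: ", cfg$spectra_dir)
    readSpectrumDir(cfg$spectra_dir)
  } else {
    simulateSpectra(cfg$design, seed = cfg$seed)
  }

  ft <- extractFeatures(set, scheme, normalize = cfg$normalize,
                        window = cfg$window, polyorder = cfg$polyorder)
  paths <- list(features = file.path(cfg$outdir, "features.csv"))
  writeFeatureTable(ft, paths$features, overwrite = TRUE)

  uv <- univariateAnalysis(ft, wt_label = cfg$wt_label, alpha = cfg$alpha,
                           outlier_threshold = cfg$outlier_threshold)
  paths$univariate <- file.path(cfg$outdir, "univariate.csv")
  write.csv(uv$table, paths$univariate, row.names = FALSE)

  uv_sub <- NULL
  if (!is.null(cfg$keep_samples)) {
    uv_sub <- subsetRerun(ft, cfg$keep_samples, wt_label = cfg$wt_label,
                          alpha = cfg$alpha,
                          outlier_threshold = cfg$outlier_threshold)
    paths$univariate_subset <- file.path(cfg$outdir, "univariate_subset.csv")
    write.csv(uv_sub$table, paths$univariate_subset, row.names = FALSE)
  }

  ## multivariate analysis runs on normalized spectra
  nset <- normalizeSet(set, if (cfg$normalize == "none") "minmax"
                       else cfg$normalize)
  region_names <- cfg$regions
  if (is.null(region_names)) region_names <- schemeRegions(scheme)$name
  ords <- list()
  for (rn in region_names) {
    region <- getRegion(scheme, rn)
    ord <- ordinateRegion(nset, region,
                          pca_observations = cfg$pca_observations)
    ords[[rn]] <- ord
    pre <- file.path(cfg$outdir, rn)
    exportDendrogram(ord$hca, pre)
    write.csv(data.frame(observation = rownames(ord$pca$scores),
                         ord$pca$scores, check.names = FALSE),
              paste0(pre, "_scores.csv"), row.names = FALSE)
    write.csv(data.frame(wavenumber = as.numeric(rownames(ord$pca$loadings)),
                         ord$pca$loadings, check.names = FALSE),
              paste0(pre, "_loadings.csv"), row.names = FALSE)
    write.csv(data.frame(component = seq_along(ord$pca$explained),
                         proportion = ord$pca$explained),
              paste0(pre, "_explained.csv"), row.names = FALSE)
  }

  manifest <- list(
    package = "atrprofiler",
    version = as.character(packageVersion("atrprofiler")),
    seed = cfg$seed,
    spectra_dir = cfg$spectra_dir,
    simulated = is.null(cfg$spectra_dir),
    normalize = cfg$normalize,
    window = cfg$window,
    polyorder = cfg$polyorder,
    wt_label = cfg$wt_label,
    alpha = cfg$alpha,
    outlier_threshold = cfg$outlier_threshold,
    keep_samples = cfg$keep_samples,
    regions = region_names,
    pca_observations = cfg$pca_observations,
    n_spectra = ncol(set)
  )
  paths$manifest <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  invisible(list(set = set, features = ft, univariate = uv,
                 univariate_subset = uv_sub, ordinations = ords,
                 paths = paths))
}
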