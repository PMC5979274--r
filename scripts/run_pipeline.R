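#!/usr/bin/env Rscript
# Thin command-line wrapper over the atrprofiler package:
#   Rscript scripts/run_pipeline.R <simulate|extract|stats|hca|pca|run-all> [options]

suppressMessages({
  library(atrprofiler)
  library(optparse)
})

usage <- function() {
  cat("usage: Rscript scripts/run_pipeline.R <command> [options]\n",
      "commands: simulate extract stats hca pca run-all\n", sep = "")
  quit(status = 2)
}

argv <- commandArgs(trailingOnly = TRUE)
if (!length(argv)) usage()
cmd <- argv[1L]
rest <- argv[-1L]

opts <- list(
  make_option("--spectra", type = "character", default = NULL,
              help = "directory of per-spectrum CSV files"),
  make_option("--design", type = "character", default = NULL,
              help = "synthetic design JSON (default: built-in design)"),
  make_option("--scheme", type = "character", default = NULL,
              help = "region scheme JSON (default: built-in alfalfa scheme)"),
  make_option("--features", type = "character", default = NULL,
              help = "feature table CSV (for the stats command)"),
  make_option("--out", type = "character", default = "results",
              help = "output directory or file prefix [default %default]"),
  make_option("--seed", type = "integer", default = 1L,
              help = "simulation seed [default %default]"),
  make_option("--region", type = "character", default = "CHO",
              help = "region name for hca/pca [default %default]"),
  make_option("--normalize", type = "character", default = "minmax",
              help = "normalization: minmax|offset|none [default %default]"),
  make_option("--window", type = "integer", default = 9L,
              help = "Savitzky-Golay window [default %default]"),
  make_option("--polyorder", type = "integer", default = 3L,
              help = "Savitzky-Golay polynomial order [default %default]"),
  make_option("--wt-label", type = "character", default = "WT",
              dest = "wt_label", help = "wild-type label [default %default]"),
  make_option("--alpha", type = "double", default = 0.05,
              help = "significance level [default %default]"),
  make_option("--outlier-threshold", type = "double", default = 2.5,
              dest = "outlier_threshold",
              help = "studentized-residual cutoff [default %default]"),
  make_option("--keep-samples", type = "character", default = NULL,
              dest = "keep_samples",
              help = "comma-separated sample ids for a subset rerun")
)
opt <- tryCatch(parse_args(OptionParser(option_list = opts), args = rest),
                error = function(e) { message(conditionMessage(e)); usage() })

fail <- function(...) { message("error: ", ...); quit(status = 2) }

loadSpectra <- function() {
  if (!is.null(opt$spectra)) {
    if (!dir.exists(opt$spectra)) fail("spectra directory not found: ",
                                       opt$spectra)
    readSpectrumDir(opt$spectra)
  } else {
    design <- if (is.null(opt$design)) defaultDesign() else
      loadDesign(opt$design)
    simulateSpectra(design, seed = opt$seed)
  }
}
scheme <- if (is.null(opt$scheme)) defaultAlfalfaScheme() else
  loadScheme(opt$scheme)

status <- tryCatch({
  switch(cmd,
    "simulate" = {
      design <- if (is.null(opt$design)) defaultDesign() else
        loadDesign(opt$design)
      set <- simulateSpectra(design, seed = opt$seed)
      writeSpectrumSet(set, opt$out, overwrite = TRUE)
      cat("wrote", ncol(set), "spectra to", opt$out, "\n")
      0L
    },
    "extract" = {
      set <- loadSpectra()
      ft <- extractFeatures(set, scheme, normalize = opt$normalize,
                            window = opt$window, polyorder = opt$polyorder)
      writeFeatureTable(ft, opt$out, overwrite = TRUE)
      cat("wrote", nrow(ft), "feature rows to", opt$out, "\n")
      0L
    },
    "stats" = {
      ft <- if (!is.null(opt$features)) readFeatureTable(opt$features) else
        extractFeatures(loadSpectra(), scheme, normalize = opt$normalize,
                        window = opt$window, polyorder = opt$polyorder)
      keep <- if (!is.null(opt$keep_samples))
        strsplit(opt$keep_samples, ",")[[1L]] else NULL
      uv <- if (is.null(keep)) {
        univariateAnalysis(ft, wt_label = opt$wt_label, alpha = opt$alpha,
                           outlier_threshold = opt$outlier_threshold)
      } else {
        subsetRerun(ft, keep, wt_label = opt$wt_label, alpha = opt$alpha,
                    outlier_threshold = opt$outlier_threshold)
      }
      write.csv(uv$table, opt$out, row.names = FALSE)
      cat("wrote", nrow(uv$table), "feature results to", opt$out, "\n")
      0L
    },
    "hca" = ,
    "pca" = {
      set <- normalizeSet(loadSpectra(),
                          if (opt$normalize == "none") "minmax" else
                            opt$normalize)
      region <- getRegion(scheme, opt$region)
      ord <- ordinateRegion(set, region)
      if (cmd == "hca") {
        exportDendrogram(ord$hca, opt$out)
        cat("wrote", paste0(opt$out, ".nwk"), "\n")
      } else {
        write.csv(data.frame(observation = rownames(ord$pca$scores),
                             ord$pca$scores, check.names = FALSE),
                  paste0(opt$out, "_scores.csv"), row.names = FALSE)
        write.csv(loadingProfile(ord$pca, 1L),
                  paste0(opt$out, "_pc1_loadings.csv"), row.names = FALSE)
        write.csv(data.frame(component = seq_along(ord$pca$explained),
                             proportion = ord$pca$explained),
                  paste0(opt$out, "_explained.csv"), row.names = FALSE)
        cat("wrote PCA tables with prefix", opt$out, "\n")
      }
      0L
    },
    "run-all" = {
      design <- if (is.null(opt$design)) defaultDesign() else
        loadDesign(opt$design)
      keep <- if (!is.null(opt$keep_samples))
        strsplit(opt$keep_samples, ",")[[1L]] else NULL
      cfg <- pipelineConfig(
        outdir = opt$out, seed = opt$seed, spectra_dir = opt$spectra,
        design = design, scheme = scheme, normalize = opt$normalize,
        window = opt$window, polyorder = opt$polyorder,
        wt_label = opt$wt_label, alpha = opt$alpha,
        outlier_threshold = opt$outlier_threshold, keep_samples = keep)
      runPipeline(cfg)
      cat("pipeline artifacts written under", opt$out, "\n")
      0L
    },
    { message("unknown command: ", cmd); 2L }
  )
}, error = function(e) { message("error [", cmd, "]: ",
                                 conditionMessage(e)); 2L })
quit(status = status)
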