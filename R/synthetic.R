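#' Default synthetic band set
#'
#' Gaussian bands at the 18 nominal peak positions of
#' [defaultAlfalfaScheme()]. Base (wild-type) amplitudes are set to the
#' scale of baseline-corrected heights observed in normalized alfalfa
#' tissue spectra; widths are 12 cm^-1 except in the congested
#' total-carbohydrate triplet TC1/TC2/TC3 (8 cm^-1) — so TC2/TC3
#' genuinely merge and exercise the second-derivative path, and the
#' amide I envelope components alpha-helix/beta-sheet overlap by
#' construction.
#'
#' @return data.frame with columns `name`, `center`, `sigma`, `amplitude`,
#'   `shape`.
#' @export
defaultBands <- function() {
  data.frame(
    name = c("TC1", "TC2", "TC3", "TC4", "CEC",
             "STC1", "STC2", "STC3", "STC4",
             "AmideII", "beta_sheet", "AmideI", "alpha_helix",
             "CCO", "SyCH2", "SyCH3", "AsCH2", "AsCH3"),
    center = c(1026, 1074, 1104, 1149, 1237,
               1317, 1370, 1397, 1453,
               1540, 1629, 1649, 1653,
               1733, 2850, 2872, 2920, 2955),
    sigma = c(8, 8, 8, 12, 12,
              12, 12, 12, 12,
              12, 12, 12, 12,
              12, 12, 12, 12, 12),
    amplitude = c(0.65, 0.50, 0.34, 0.16, 0.08,
                  0.09, 0.15, 0.16, 0.13,
                  0.27, 0.15, 0.36, 0.35,
                  0.06, 0.10, 0.06, 0.18, 0.06),
    shape = "gaussian",
    stringsAsFactors = FALSE
  )
}

#' Default synthetic study design
#'
#' The sampling design of the alfalfa gene-silencing study: WT n = 4,
#' TT8i n = 5, HB12i n = 11 biological samples, 5 subsample spectra each
#' (100 spectra total), on a 4000-700 cm^-1 grid at 2 cm^-1 spacing.
#'
#' Genotype band-amplitude multipliers are calibrated to the published
#' group-mean tables: in every peak-height row whose Tukey letters show
#' any genotype separation, each transgenic genotype's multiplier is its
#' printed group mean divided by the WT mean (e.g. HB12i STC3
#' 0.230/0.164 = 1.402, TT8i STC3 0.187/0.164 = 1.140, HB12i SyCH2
#' 0.133/0.101 = 1.317); rows without letter separation keep multiplier
#' 1. WT is the reference genotype with all multipliers 1. The subset of
#' these effects in which the genotype's letter group excludes WT's —
#' the differences the tables actually demonstrate against the wild type
#' — is returned by [plantedDirections()].
#'
#' Noise defaults (two-level error structure mirroring the nested model):
#' multiplicative per-band sample random effect SD 0.02, additive
#' subsample white noise SD 0.0015 absorbance units, and random quadratic
#' baseline drift with coefficient SDs (0.01, 0.01, 0.01) over the scaled
#' grid — together giving genotype-mean SEMs of the same order as the
#' published SEM columns (about 0.001-0.01 on heights).
#'
#' @return A [SyntheticDesign-class].
#' @examples
#' d <- defaultDesign()
#' sum(d@genotypes$n_samples) * d@subsamples  # 100 spectra
#' @export
defaultDesign <- function() {
  bands <- defaultBands()
  genotypes <- data.frame(
    genotype = c("WT", "HB12i", "TT8i"),
    n_samples = c(4L, 11L, 5L),
    stringsAsFactors = FALSE
  )
  mult <- matrix(1, nrow = 3L, ncol = nrow(bands),
                 dimnames = list(genotypes$genotype, bands$name))
  ## HB12i vs WT mean ratios where HB12i's letters exclude WT's
  mult["HB12i", "TC1"] <- 0.612 / 0.646
  mult["HB12i", "TC2"] <- 0.550 / 0.498
  mult["HB12i", "TC3"] <- 0.381 / 0.338
  mult["HB12i", "STC1"] <- 0.106 / 0.093
  mult["HB12i", "STC2"] <- 0.162 / 0.151
  mult["HB12i", "STC3"] <- 0.230 / 0.164
  mult["HB12i", "STC4"] <- 0.168 / 0.131
  mult["HB12i", "beta_sheet"] <- 0.386 / 0.335
  mult["HB12i", "SyCH2"] <- 0.133 / 0.101
  mult["HB12i", "AsCH2"] <- 0.237 / 0.184
  ## TT8i vs WT
  mult["TT8i", "TC1"] <- 0.606 / 0.646
  mult["TT8i", "TC2"] <- 0.533 / 0.498
  mult["TT8i", "TC3"] <- 0.373 / 0.338
  mult["TT8i", "STC1"] <- 0.100 / 0.093
  mult["TT8i", "STC2"] <- 0.152 / 0.151
  mult["TT8i", "STC3"] <- 0.187 / 0.164
  mult["TT8i", "STC4"] <- 0.143 / 0.131
  mult["TT8i", "beta_sheet"] <- 0.369 / 0.335
  mult["TT8i", "SyCH2"] <- 0.116 / 0.101
  mult["TT8i", "AsCH2"] <- 0.206 / 0.184
  new("SyntheticDesign",
    bands = bands,
    genotypes = genotypes,
    multipliers = mult,
    subsamples = 5L,
    sample_sd = 0.02,
    noise_sd = 0.0015,
    drift_sd = c(0.01, 0.01, 0.01),
    grid = c(700, 4000, 2)
  )
}

#' The planted genotype effects of a design
#'
#' @param design a [SyntheticDesign-class].
#' @return data.frame `band`, `genotype`, `multiplier` for every
#'   multiplier different from 1 (the effects a recovery analysis should
#'   detect, with `multiplier > 1` meaning the band is amplified relative
#'   to the reference genotype).
#' @export
plantedEffects <- function(design) {
  stopifnot(is(design, "SyntheticDesign"))
  m <- design@multipliers
  idx <- which(m != 1, arr.ind = TRUE)
  data.frame(
    band = colnames(m)[idx[, 2L]],
    genotype = rownames(m)[idx[, 1L]],
    multiplier = m[idx],
    stringsAsFactors = FALSE
  )
}

#' Table-demonstrated genotype effect directions
#'
#' The subset of the default design's planted effects whose Tukey letter
#' group in the published tables excludes the wild type's letters — i.e.
#' the band-height differences the source tables actually demonstrate
#' against WT, and therefore the effects a recovery analysis should be
#' able to re-detect in direction. `direction` is +1 for bands amplified
#' relative to WT and -1 for bands reduced.
#'
#' @return data.frame `band`, `genotype`, `direction`.
#' @export
plantedDirections <- function() {
  data.frame(
    band = c("TC1", "TC2", "TC3", "STC1", "STC2", "STC3", "STC4",
             "beta_sheet", "SyCH2", "AsCH2",
             "TC1", "TC2", "TC3", "STC3", "beta_sheet"),
    genotype = c(rep("HB12i", 10), rep("TT8i", 5)),
    direction = c(-1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
                  -1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

.bandShape <- function(w, center, sigma, shape) {
  if (shape == "lorentzian") {
    1 / (1 + ((w - center) / sigma)^2)
  } else {
    exp(-(w - center)^2 / (2 * sigma^2))
  }
}

#' Simulate a spectrum set from a design
#'
#' For each biological sample one multiplicative random effect per band is
#' drawn; each subsample spectrum is the sum of its genotype's bands
#' (amplitude x genotype multiplier x (1 + sample effect)), plus a random
#' quadratic baseline drift, plus white noise. Bit-identical given the
#' same seed.
#'
#' @param design a [SyntheticDesign-class] (default [defaultDesign()]).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return An [IRSpectrumSet-class] with sample ids `W1..`, `H1..`,
#'   `T1..` and subsample ids `1..k`.
#' @export
simulateSpectra <- function(design = defaultDesign(), seed = NULL) {
  stopifnot(is(design, "SyntheticDesign"))
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(design@grid[1L], design@grid[2L], by = design@grid[3L])
  x <- (grid - min(grid)) / (max(grid) - min(grid))  # scaled for drift
  bands <- design@bands
  shapes <- vapply(seq_len(nrow(bands)), function(b)
    .bandShape(grid, bands$center[b], bands$sigma[b], bands$shape[b]),
    numeric(length(grid)))
  prefix <- function(g) {
    p <- toupper(substr(g, 1L, 1L))
    if (p == "") "S" else p
  }
  spectra <- list()
  for (gi in seq_len(nrow(design@genotypes))) {
    g <- design@genotypes$genotype[gi]
    amps0 <- bands$amplitude * design@multipliers[gi, ]
    for (j in seq_len(design@genotypes$n_samples[gi])) {
      u <- rnorm(nrow(bands), 0, design@sample_sd)
      amps <- amps0 * (1 + u)
      for (k in seq_len(design@subsamples)) {
        drift <- rnorm(1, 0, design@drift_sd[1L]) +
          rnorm(1, 0, design@drift_sd[2L]) * x +
          rnorm(1, 0, design@drift_sd[3L]) * x^2
        a <- as.vector(shapes %*% amps) + drift +
          rnorm(length(grid), 0, design@noise_sd)
        spectra[[length(spectra) + 1L]] <- IRSpectrum(
          grid, a, genotype = g,
          sample_id = paste0(prefix(g), j),
          subsample_id = as.character(k)
        )
      }
    }
  }
  IRSpectrumSet(spectra)
}
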