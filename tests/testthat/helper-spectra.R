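# Synthetic fixtures built in code: Gaussian band mixtures on even grids.

gauss <- function(w, center, sigma, A = 1) {
  A * exp(-(w - center)^2 / (2 * sigma^2))
}

# a spectrum made of Gaussian bands plus an optional linear baseline
bandSpectrum <- function(grid, centers, sigmas, amps, slope = 0,
                         intercept = 0, genotype = "WT", sample_id = "W1",
                         subsample_id = "1") {
  a <- intercept + slope * grid
  for (i in seq_along(centers))
    a <- a + gauss(grid, centers[i], sigmas[i], amps[i])
  IRSpectrum(grid, a, genotype, sample_id, subsample_id)
}

# feature table drawn directly from the nested model
# Y_ijk = mu + geno_i + b_ij + e_ijk  (no spectra involved)
nestedTable <- function(means, n_samples, subsamples = 5,
                        sigma_s = 0.01, sigma_e = 0.005,
                        feature = "y") {
  rows <- list()
  sid <- 0
  for (g in names(means)) {
    for (j in seq_len(n_samples[[g]])) {
      sid <- sid + 1
      b <- rnorm(1, 0, sigma_s)
      for (k in seq_len(subsamples)) {
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = g, sample_id = paste0("S", sid),
          subsample_id = as.character(k),
          value = means[[g]] + b + rnorm(1, 0, sigma_e),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  ft <- do.call(rbind, rows)
  names(ft)[names(ft) == "value"] <- feature
  ft
}

# the alfalfa study design sizes
paperN <- c(WT = 4, HB12i = 11, TT8i = 5)
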