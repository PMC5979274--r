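#' Construct a RegionScheme
#'
#' Low-level constructor; most users start from [defaultAlfalfaScheme()] or
#' [loadScheme()]. The object is validated on construction.
#'
#' @param regions,peaks,splits,ratios data.frames as documented in
#'   [RegionScheme-class].
#' @return A [RegionScheme-class].
#' @export
.emptySplits <- function() {
  data.frame(name = character(), region = character(),
             split_at = numeric(), part_high = character(),
             part_low = character(), stringsAsFactors = FALSE)
}

.emptyRatios <- function() {
  data.frame(name = character(), numerator = character(),
             denominator = character(), stringsAsFactors = FALSE)
}

.featureNameList <- function(pk, rg, sp, with_ratios = TRUE, rt = NULL) {
  areas <- rg$area_name
  out <- c(pk$name, areas[!is.na(areas)],
           as.vector(t(sp[, c("part_high", "part_low")])))
  if (with_ratios) out <- c(out, rt$name)
  out
}

RegionScheme <- function(regions, peaks, splits = .emptySplits(),
                         ratios = .emptyRatios()) {
  if (!"area_name" %in% names(regions)) regions$area_name <- NA_character_
  if (!"mode" %in% names(peaks)) peaks$mode <- "apex"
  if (!"search_halfwidth" %in% names(peaks)) peaks$search_halfwidth <- 8
  new("RegionScheme",
    regions = as.data.frame(regions, stringsAsFactors = FALSE),
    peaks = as.data.frame(peaks, stringsAsFactors = FALSE),
    splits = as.data.frame(splits, stringsAsFactors = FALSE),
    ratios = as.data.frame(ratios, stringsAsFactors = FALSE)
  )
}

#' Feature names declared by a scheme, in declaration order
#'
#' Peak heights, then region areas, then split part areas, then ratios —
#' the column order of the table produced by [extractFeatures()].
#'
#' @param scheme a [RegionScheme-class].
#' @param with_ratios include ratio features?
#' @return character vector of feature names.
#' @export
featureNames <- function(scheme, with_ratios = TRUE) {
  .featureNameList(scheme@peaks, scheme@regions, scheme@splits,
                   with_ratios, scheme@ratios)
}

#' Validate a region scheme
#'
#' Checks every structural invariant: region bounds ordered high > low,
#' unique names across the feature namespace, peaks inside their regions,
#' split points strictly inside their regions, and every cross-reference
#' (peak region, split region, ratio operands) resolving.
#'
#' @param scheme a [RegionScheme-class], or a plain list with elements
#'   `regions`, `peaks`, `splits`, `ratios` (so candidate schemes can be
#'   checked before construction).
#' @return character vector of violations; empty when the scheme is valid.
#' @export
validateScheme <- function(scheme) {
  if (is(scheme, "RegionScheme")) {
    rg <- scheme@regions; pk <- scheme@peaks
    sp <- scheme@splits; rt <- scheme@ratios
  } else {
    rg <- as.data.frame(scheme$regions)
    pk <- as.data.frame(scheme$peaks)
    sp <- if (is.null(scheme$splits)) .emptySplits() else
      as.data.frame(scheme$splits)
    rt <- if (is.null(scheme$ratios)) .emptyRatios() else
      as.data.frame(scheme$ratios)
    if (!"area_name" %in% names(rg)) rg$area_name <- NA_character_
    if (!"mode" %in% names(pk)) pk$mode <- "apex"
  }
  v <- character()
  if (any(bad <- rg$high <= rg$low))
    v <- c(v, sprintf("region %s: inverted bounds (high <= low)",
                      rg$name[bad]))
  ## regions and features are separate namespaces (a single-peak region
  ## conventionally shares its peak's name, e.g. CEC)
  if (anyDuplicated(rg$name))
    v <- c(v, sprintf("duplicate region name: %s",
                      unique(rg$name[duplicated(rg$name)])))
  nm <- .featureNameList(pk, rg, sp, TRUE, rt)
  if (anyDuplicated(nm))
    v <- c(v, sprintf("duplicate feature name: %s",
                      unique(nm[duplicated(nm)])))
  for (i in seq_len(nrow(pk))) {
    r <- rg[rg$name == pk$region[i], , drop = FALSE]
    if (nrow(r) != 1L) {
      v <- c(v, sprintf("peak %s: unknown region %s", pk$name[i],
                        pk$region[i]))
    } else if (pk$nominal[i] > r$high || pk$nominal[i] < r$low) {
      v <- c(v, sprintf("peak %s: nominal %.0f outside region %s (%.0f-%.0f)",
                        pk$name[i], pk$nominal[i], r$name, r$high, r$low))
    }
    if (!pk$mode[i] %in% c("apex", "second_derivative"))
      v <- c(v, sprintf("peak %s: unknown mode %s", pk$name[i], pk$mode[i]))
  }
  for (i in seq_len(nrow(sp))) {
    r <- rg[rg$name == sp$region[i], , drop = FALSE]
    if (nrow(r) != 1L) {
      v <- c(v, sprintf("split %s: unknown region %s", sp$name[i],
                        sp$region[i]))
    } else if (sp$split_at[i] >= r$high || sp$split_at[i] <= r$low) {
      v <- c(v, sprintf("split %s: split point %.0f not strictly inside %s",
                        sp$name[i], sp$split_at[i], r$name))
    }
  }
  operands <- .featureNameList(pk, rg, sp, FALSE)
  for (i in seq_len(nrow(rt))) {
    for (op in c("numerator", "denominator"))
      if (!rt[[op]][i] %in% operands)
        v <- c(v, sprintf("ratio %s: unresolved operand %s", rt$name[i],
                          rt[[op]][i]))
  }
  v
}

#' The default alfalfa region scheme
#'
#' The region/peak/split/ratio layout for structural profiling of alfalfa
#' tissue spectra:
#'
#' * regions (two-point baseline endpoints, cm^-1): carbohydrate CHO
#'   1484-941, total carbohydrate TC 1178-941, structural carbohydrate STC
#'   1484-1178, cellulosic compounds CEC 1283-1178, Amide 1710-1484,
#'   carbonyl ester CCO 1781-1710, CH-stretch ASCC 3000-2761, plus the
#'   fingerprint (1800-800) and whole (4000-700) windows used only for
#'   multivariate analysis;
#' * 18 peaks: TC1 1026, TC2 1074, TC3 1104, TC4 1149, CEC 1237,
#'   STC1 1317, STC2 1370, STC3 1397, STC4 1453, amide I 1649,
#'   amide II 1540, alpha-helix 1653, beta-sheet 1629, CCO 1733,
#'   SyCH2 2850, SyCH3 2872, AsCH2 2920, AsCH3 2955;
#' * region areas TCA, STCA, CECA, AA, CCOA, ASCCA, with the total amide
#'   area AA split at 1575 into amide I area (AIA) and amide II area (AIIA);
#' * amide-region ratios alpha-helix/beta-sheet, amide I/amide II,
#'   AIA/AIIA, AIA/AA.
#'
#' Peaks known to overlap their neighbours (TC2/TC3 in the congested
#' carbohydrate triplet; amide I/II which merge in alfalfa; alpha-helix and
#' beta-sheet inside the amide I envelope) are located on the
#' second-derivative minimum; well-separated peaks use the absorbance apex.
#' The search half-width is 8 cm^-1 around each nominal position.
#'
#' @return A [RegionScheme-class] that passes [validateScheme()] with zero
#'   violations.
#' @examples
#' sch <- defaultAlfalfaScheme()
#' validateScheme(sch)
#' @export
defaultAlfalfaScheme <- function() {
  regions <- data.frame(
    name = c("CHO", "TC", "STC", "CEC", "Amide", "CCO", "ASCC",
             "fingerprint", "whole"),
    high = c(1484, 1178, 1484, 1283, 1710, 1781, 3000, 1800, 4000),
    low = c(941, 941, 1178, 1178, 1484, 1710, 2761, 800, 700),
    area_name = c(NA, "TCA", "STCA", "CECA", "AA", "CCOA", "ASCCA", NA, NA),
    stringsAsFactors = FALSE
  )
  d2 <- "second_derivative"
  peaks <- data.frame(
    name = c("TC1", "TC2", "TC3", "TC4", "CEC",
             "STC1", "STC2", "STC3", "STC4",
             "AmideI", "AmideII", "alpha_helix", "beta_sheet",
             "CCO", "SyCH2", "SyCH3", "AsCH2", "AsCH3"),
    nominal = c(1026, 1074, 1104, 1149, 1237,
                1317, 1370, 1397, 1453,
                1649, 1540, 1653, 1629,
                1733, 2850, 2872, 2920, 2955),
    region = c(rep("TC", 4), "CEC", rep("STC", 4), rep("Amide", 4),
               "CCO", rep("ASCC", 4)),
    mode = c("apex", d2, d2, "apex", "apex",
             "apex", "apex", "apex", "apex",
             d2, d2, d2, d2,
             "apex", "apex", "apex", "apex", "apex"),
    search_halfwidth = 8,
    stringsAsFactors = FALSE
  )
  splits <- data.frame(
    name = "AA_split", region = "Amide", split_at = 1575,
    part_high = "AIA", part_low = "AIIA", stringsAsFactors = FALSE
  )
  ratios <- data.frame(
    name = c("AmideI_AmideII", "alpha_helix_beta_sheet", "AIA_AIIA",
             "AIA_AA"),
    numerator = c("AmideI", "alpha_helix", "AIA", "AIA"),
    denominator = c("AmideII", "beta_sheet", "AIIA", "AA"),
    stringsAsFactors = FALSE
  )
  RegionScheme(regions, peaks, splits, ratios)
}

#' Save a region scheme as JSON
#'
#' @param scheme a [RegionScheme-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
saveScheme <- function(scheme, path) {
  obj <- list(
    regions = scheme@regions,
    peaks = scheme@peaks,
    splits = scheme@splits,
    ratios = scheme@ratios
  )
  jsonlite::write_json(obj, path, dataframe = "rows", digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Load a region scheme from JSON
#'
#' Reads the document written by [saveScheme()] (top-level keys `regions`,
#' `peaks`, `splits`, `ratios`) and validates it; any invariant violation is
#' an error naming the violations.
#'
#' @param path JSON file path.
#' @return A [RegionScheme-class].
#' @export
loadScheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("regions", "peaks"))
    if (is.null(obj[[k]]) || !nrow(as.data.frame(obj[[k]])))
      stop("scheme file lacks ", k)
  splits <- if (!is.null(obj$splits) && length(obj$splits))
    as.data.frame(obj$splits) else NULL
  ratios <- if (!is.null(obj$ratios) && length(obj$ratios))
    as.data.frame(obj$ratios) else NULL
  args <- list(regions = as.data.frame(obj$regions),
               peaks = as.data.frame(obj$peaks))
  if (!is.null(splits) && nrow(splits)) args$splits <- splits
  if (!is.null(ratios) && nrow(ratios)) args$ratios <- ratios
  do.call(RegionScheme, args)
}
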