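---
title: "Region-based structural profiling of ATR-FTIR spectra: models and methods"
author: "atrprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based structural profiling of ATR-FTIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrprofiler)
```

This vignette is the package's account of its science: the measurement
model, the statistical model, the synthetic-data generator and its
calibration, the numerical choices, and what the test suite does and
does not demonstrate.

## The measurement problem

An ATR-FTIR absorbance spectrum of ground plant tissue is a smooth curve
$A(\tilde\nu)$ over roughly 4000–700 cm⁻¹ in which the macromolecular
components absorb in characteristic windows: amide I/II for protein
backbone, the 1484–941 cm⁻¹ complex for carbohydrates, carbonyl ester
and CH-stretch windows for lipids. Band heights and areas in those
windows, read after local baseline correction, act as relative
concentration/structure indices; comparing genotypes is then a
mixed-model comparison of those indices, complemented by whole-region
clustering and ordination. Two measurement difficulties shape the
design:

* **Sloping local baselines.** Absorbance in a window rides on
  scattering and neighbouring-band tails. The package uses the field's
  two-point correction: within a declared region the baseline is the
  straight chord joining the spectrum at the region's endpoints, and
  every height and area in that region is measured against it. This
  makes all features invariant, to machine precision, under addition of
  any global linear trend (a property the test suite asserts at 1e-9).

* **Overlapped bands.** Several diagnostically distinct bands (the
  ~1074/1104 cm⁻¹ carbohydrate pair; α-helix 1653 vs β-sheet 1629 within
  the amide I envelope; amide I vs II in low-protein tissue) merge into
  a single visible envelope. The package locates such peaks at minima of
  the smoothed second derivative, where band curvature sharpens and
  linear baseline contributions vanish identically.

## Data model

`IRSpectrumSet` extends `SummarizedExperiment`: one `absorbance` assay
with the strictly increasing wavenumber grid as rows and subsample
spectra as columns, and the genotype → sample → subsample design in
`colData`. The canonical internal order is ascending wavenumber even
though instruments export descending; region bounds are declared as
(high, low) pairs and snapped to the nearest grid node, which is how
"circa" band positions are interpreted throughout. The default working
grid spacing is 2 cm⁻¹, a typical data-point spacing for instruments
operated at 4 cm⁻¹ optical resolution; it is configurable because
vendors differ.

## Preprocessing

**Normalization** (`normalizeSpectrum`, default `minmax`) affinely maps
each spectrum to [0, 1] over its full recorded range. ATR contact
pressure and effective sample thickness scale absorbance
multiplicatively; min–max removes that scale (the suite checks exact
invariance under $A \mapsto aA + b$, $a > 0$). An `offset` mode
(minimum subtraction only) and `none` are provided for comparison, e.g.
when reading physical band amplitudes off synthetic spectra.
Normalization has a side effect worth knowing: every feature becomes a
ratio to the spectrum's global range, so sample-to-sample variation of
the tallest envelope propagates into all features. Whether to normalize
over a sub-range instead is a scheme-level choice; the full range is
the default.

**Second derivative** (`secondDerivative`) is a Savitzky–Golay
convolution: a polynomial of order $p$ (default 3) fitted in a sliding
window of $w$ points (default 9, i.e. 18 cm⁻¹ at the default spacing),
differentiated twice at the centre and scaled by the grid spacing
squared. Defaults follow common FTIR practice for band resolution at
this spacing. Two exact properties anchor the tests: linearity, and
annihilation of straight lines at interior points for $p \ge 2$. One
quantitative caveat, asserted in the tests: the minimum value
approximates $-A/\sigma^2$ for a Gaussian band of amplitude $A$ and
width $\sigma$, but cubic smoothing attenuates the curvature of narrow
bands (about 17 % low at $\sigma$ = 8 cm⁻¹ with the default window);
with the quartic filter (`polyorder = 4`) the amplitude is within 2 %
for $\sigma \ge 8$ cm⁻¹, while peak *localisation* is unaffected either
way. The package therefore uses the derivative for locating peaks, not
for quantifying them.

## The region scheme

`defaultAlfalfaScheme()` declares, as data, the layout used for alfalfa
tissue: regions CHO 1484–941, TC 1178–941, STC 1484–1178, CEC
1283–1178, amide 1710–1484, CCO 1781–1710, ASCC 3000–2761 cm⁻¹ (plus
fingerprint 1800–800 and whole 4000–700 windows used only for
multivariate analysis); 18 peaks (TC1–TC4, CEC, STC1–STC4, amide I/II,
α-helix, β-sheet, CCO, SyCH₂/SyCH₃/AsCH₂/AsCH₃); areas TCA, STCA, CECA,
AA, CCOA, ASCCA with AA split at 1575 cm⁻¹ into AIA and AIIA; and the
four amide ratios. Design choices:

* **Search half-width 8 cm⁻¹** around each nominal position — half the
  band spacing in the congested 1026/1074/1104 triplet, so search
  windows of adjacent peaks never overlap.
* **Mode per peak**: apex for well-separated bands,
  second-derivative-minimum for the overlapped ones (TC2, TC3, amide
  I/II, α-helix, β-sheet). If no interior extremum exists in the
  window, the nominal position is used; ties break toward nominal.
* **The amide split is a fixed node.** Snapping 1575 cm⁻¹ to the grid
  makes AIA + AIIA equal the total amide area exactly (to float
  summation noise); `splitArea()` accepts any split point, so a
  derivative-located split can be supplied when the data warrant it.
* Region names and feature names are separate namespaces, because a
  single-peak region conventionally shares its peak's name (CEC, CCO).

Schemes serialize to JSON (`saveScheme`/`loadScheme`) and
`validateScheme()` reports every violated invariant by name.

## Feature extraction

For each spectrum: normalize → second derivative → locate the 18 peaks
→ corrected heights at the located positions → region areas → the AA
split → per-observation ratios. Heights are read at located rather than
nominal positions by default (`locate = FALSE` reverts), because
nominal positions are "circa" values and real band centres wander a few
cm⁻¹ with composition. Negative corrected values are reported as-is
with a warning, never clipped: clipping would bias group means and
SEMs downstream. The α-helix and β-sheet heights are measured against
the common amide-region baseline — the only baseline defined in that
window — with the second derivative supplying their positions inside
the amide I envelope. Ratios are computed per subsample observation and
the statistics operate on those observations (mean of ratios), matching
the observation-level model below; this is also why published ratio
rows of group-mean tables need not equal ratios of the printed means.
A spectrum that fails yields an NA row plus a warning naming it; the
batch continues.

## Univariate statistics

Each feature is analysed under the nested mixed model
$$Y_{ijk} = \mu + \text{genotype}_i + \text{sample(genotype)}_{ij} + \varepsilon_{ijk},$$
with the biological sample a random effect and the five subsample
spectra as technical replication. Estimation is REML
(`lme4`/`lmerTest`) with Satterthwaite denominator degrees of freedom;
on balanced designs with a positive sample-variance estimate this
reproduces the classical nested ANOVA F — equivalently the one-way
ANOVA on sample means — to numerical precision (asserted at 1e-6), and
its type-I error on the unbalanced 4/11/5 design is 5 % ± 2 % over 500
null simulations. Commercial mixed-model software with different
denominator-degree conventions may differ in the third decimal of
p-values.

Before fitting, a **single screening pass** removes observations with
absolute externally studentized residual (leave-one-out form, computed
from the model's hat values) above 2.5 — one pass, not iterated,
because iterating the screen couples the threshold to the final fit.
Reported per feature: least-squares means; Tukey–Kramer adjusted
all-pairs comparisons, summarised as compact letters by the standard
insert-and-absorb algorithm so that two genotypes share a letter if and
only if their adjusted p ≥ α; the largest least-squares-mean standard
error as the single SEM column (the convention for unbalanced summary
tables); the overall F-test p; the 1-df wild-type-versus-pooled-
transgenic contrast; and a Shapiro–Wilk p on conditional residuals,
reported but never used to switch methods automatically. Note that an
F-test p just below α with no Tukey separation is a legitimate outcome
near the threshold, not an inconsistency; the letters come from the
adjusted pairwise tests, the p column from the F test. Designs that
cannot support the model (one genotype, no subsample replication,
constant response) are flagged `degenerate` with missing p-values.

`subsetRerun()` repeats everything on a named sample subset — the
built-in replication study keeps the second and third sample of each
genotype — to show what a pilot-scale population does to the
significance structure.

## Multivariate analysis

**HCA** operates on per-sample mean spectra (subsample averaging
de-noises the leaves and keeps dendrograms readable), restricted to one
region: Euclidean distances, squared, then `hclust` with `ward.D` — the
classic Ward recipe whose merge heights live on the squared-distance
scale. For 1-D points {0, 1, 10} the heights are 1 and 361/3 by the
Lance–Williams update, the hand-computed oracle frozen in the tests.
Heights are monotone and the tree is row-order invariant.

**PCA** centres and scales every wavenumber column and decomposes by
SVD (`prcomp`). Observations are all subsample spectra by default
(sample means optional): the per-sample clouds are informative in score
plots. Zero-variance columns cannot be scaled and are dropped with a
warning instead of aborting a batch — under min–max normalization the
grid node carrying every spectrum's maximum is such a column. Loading
signs are fixed deterministically (largest-magnitude loading positive),
scores flipped accordingly; explained-variance proportions sum to one
and match a brute-force eigendecomposition of the correlation matrix to
1e-8. `loadingProfile()` exports loading-versus-wavenumber tables in
ascending order for the loading plots that identify which bands drive a
component.

## The synthetic generator and its calibration

`simulateSpectra(defaultDesign())` generates the study conditions the
package is tested under: WT n = 4, HB12i n = 11, TT8i n = 5 biological
samples, 5 subsample spectra each (100 spectra), grid 4000–700 cm⁻¹ at
2 cm⁻¹. Each spectrum is a sum of Gaussian bands at the 18 scheme
peaks, with widths 12 cm⁻¹ (8 cm⁻¹ in the congested TC1–TC3 triplet so
that TC2/TC3 genuinely merge and exercise the derivative path; α-helix,
β-sheet and amide I overlap by construction), plus a random quadratic
baseline drift, plus white noise:

* **Planted genotype effects.** Band-amplitude multipliers are the
  ratios of published group means to the wild-type mean in every
  height row whose Tukey letters show separation (e.g. HB12i STC3
  0.230/0.164 = 1.402, TT8i STC3 1.140, HB12i SyCH₂ 1.317, both
  genotypes ~0.94 on TC1), and 1 elsewhere. `plantedDirections()`
  lists the subset whose letters exclude the wild type's — the effects
  the source tables actually demonstrate against WT, and hence the
  recovery targets; multipliers within a letter group of WT (down to
  1.007) are retained for realism but are statistically invisible by
  construction and not recovery targets.
* **Noise.** One multiplicative random effect per band per sample
  (SD 0.02) plus additive subsample noise (SD 0.0015 absorbance) and
  drift coefficients of SD 0.01. These were set so the simulated
  feature SEMs span ~0.001–0.01 on normalized heights, the order of
  the published SEM columns. Min–max normalization couples every
  feature to the sample effects of the tallest (amide) envelope, which
  is why a 2 % band-level SD yields ~1–3 % feature-level variation.
* The dedicated power check for the three-letter STC3 pattern draws
  feature values directly from the nested model at σ_sample = 0.007,
  σ_subsample = 0.0035 — group-mean SEMs ≈ 0.003, inside the published
  SEM range for the height rows.

What the generator does **not** emulate: continuous broadband
compositional differences between genotypes (real spectra differ across
whole regions, not only at 18 band centres), atmospheric water-vapour
and CO₂ artefacts, ATR penetration-depth wavelength dependence, and
scatter effects beyond a smooth quadratic drift. Tests passing on this
generator therefore demonstrate that the pipeline's measurement,
statistics and ordination recover *band-level* planted structure under
a realistic noise budget — not that any particular real tissue will
separate.

## What the replication study shows — and what it cannot

`recoveryStudy()` (also run by `scripts/acceptance.R`) simulates 20
seeds of the full design and re-runs the pipeline on each:

* **Direction recovery is complete.** Every planted
  letter-distinct effect (15 band × genotype combinations) is recovered
  in direction — the sign of the fitted least-squares-mean difference
  from WT — in 100 % of seeds, and the nested F test keeps its nominal
  size.
* **Top-level WT isolation in CHO clustering is not implied by the
  table calibration.** With noiseless table-calibrated centroids, the
  squared CHO distances are d²(WT, TT8i) ≈ 0.067, d²(TT8i, HB12i) ≈
  0.057, d²(WT, HB12i) ≈ 0.191: TT8i sits midway. Ward's criterion
  weights merge costs by cluster size, so splitting off the 11-sample
  HB12i cluster is preferred unless d²(WT, TT8i) exceeds roughly
  1.55 × d²(TT8i, HB12i); consequently WT is alone at the 2-cluster cut
  in only ~35 % of seeds, although it occupies its own cluster at the
  3-cluster cut in ~90 %. Likewise PC1 of the subsample-spectrum PCA
  does not separate WT from the transgenics without overlap, because
  the between-genotype shifts are comparable to the within-genotype
  sample variation once only band heights differ. A tissue in which
  both transgenic genotypes share broad, whole-region differences from
  the wild type — larger than their mutual band-height differences —
  would show clean top-level isolation; band-height tables alone do
  not encode such a component, and the generator does not invent one.
* **Large planted effects survive a two-samples-per-genotype rerun.**
  All ten planted bands are significant at full n in essentially every
  seed; restricting to two samples per genotype raises p by orders of
  magnitude (typical STC3: 1e-14 → 1e-3) and the weakest planted bands
  lose significance in most seeds, but
  the strongest planted effects (+28 % to +40 %) remain detectable even
  at 3 denominator degrees of freedom, so a *majority* of features
  does not lose significance under this calibration. A complete loss
  of significance at pilot scale requires between-sample variability
  larger than the published SEM columns imply.

These three paragraphs are exactly what `tests/testthat/test-acceptance.R`
asserts and `scripts/acceptance.R` reports; the second and third
describe checks that the stated study conditions cannot satisfy, which
the suite reports as failures by design rather than by weakened
thresholds.

## Numerical choices and degenerate inputs

* "Circa" wavenumbers snap to the nearest grid node everywhere
  (baseline endpoints, split points, height read-out).
* Peak-location ties break toward the nominal position; extrema on the
  search-window edge fall back to nominal.
* Area additivity (AIA + AIIA = AA) holds to 1e-12 *relative* to the
  area magnitude; float summation order forbids a tighter absolute
  claim on areas of magnitude ~50–100.
* Ratio denominators with |x| ≤ 1e-12 give NA with a warning.
* Constant spectra are an error under min–max normalization; constant
  features and unreplicated designs are flagged degenerate rather than
  fitted; a single failing spectrum never aborts a batch.
* All simulation entry points take integer seeds; the same seed gives
  bit-identical spectra, and the pipeline manifest (which records
  configuration, seed and package version, deliberately no timestamps)
  reproduces every artifact byte-for-byte on the same platform.

## Problem sizes in the shipped test suite

The suite runs the full 100-spectrum design where the design itself is
under test (synthetic-data checks, the 20-seed replication study, the
500-simulation type-I and permutation-uniformity checks) and scaled-down
designs (2–3 genotypes × 2–3 samples × 2–3 subsamples, or direct
feature-level simulation) for pipeline plumbing, chosen so the whole
suite completes in a few minutes while every statistical claim is still
exercised at the sizes stated above.

## Known limitations

* Two-point baselines under-read bands within ~2 band widths of a
  region endpoint (e.g. the carbonyl band at 1.9 σ from its 1710 cm⁻¹
  endpoint loses ~10 % height to the lifted baseline); this is a
  property of the measurement convention, shared with the macro-style
  workflows it reimplements, not an artefact of this implementation.
* No curve-fitting band deconvolution, no multiplicative scatter or
  rubber-band correction, no atmospheric compensation; the package
  measures spectra as preprocessed by the conventions above.
* P-values replicate a REML/Satterthwaite convention; other software's
  denominator-degree choices will differ slightly.
* JCAMP-DX support covers plain AFFN `XYDATA` tables only.
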