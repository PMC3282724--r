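---
title: "Modeling successional vegetation attributes from image texture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling successional vegetation attributes from image texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glcmveg)
```

## The problem

Secondary (successional) tropical dry forest forms a mosaic of
differently-aged fallows, and its structure — basal area, canopy cover,
height, species diversity — changes continuously with time since
abandonment. Estimating these attributes over whole landscapes from field
plots alone is infeasible. The premise of this package is that in
very-high-resolution imagery (pixels of a few metres) the *texture* of a
stand — the spatial variation of its pixel values — carries that
information: young stands are spectrally heterogeneous because bare soil
shows through an open canopy, while older stands present a closed, more
uniform canopy. Texture statistics computed over a window matched to the
plot size should therefore decline as stands develop, and linear models on
a handful of texture variables should describe and predict stand
attributes.

`glcmveg` implements that analysis end to end: spectral index layers,
first-order and gray-level co-occurrence matrix (GLCM) texture features,
per-hectare stand attributes from nested stem inventories, exhaustive
best-subset linear modeling with AICc comparison, permutation null
distributions of the maximal R², and leave-two-out cross-validation —
plus a synthetic successional-scene generator so that every stage is
testable without external imagery.

## The synthetic landscape generator

No imagery or plot coordinates are distributed with the reference study,
so the package generates its own study systems. Each scene is a grid of
rectangular stands (default side 20 px ≈ 52 m at the 2.6 m default pixel,
i.e. ~2,700 m², the upper end of realistic smallholder field sizes). Pixel
reflectance in each band mixes two endmembers,

\[ \rho = c\,\rho_{\mathrm{canopy}} + (1 - c)\,\rho_{\mathrm{soil}} + \varepsilon, \]

where the per-pixel canopy-cover fraction \(c\) is Beta-distributed around
the stand mean \(A(1 - e^{-r\,\mathrm{age}})\) (defaults \(A = 0.95\),
\(r = 0.12\,\mathrm{yr}^{-1}\)) with variance \(v_0 e^{-d\,\mathrm{age}}\)
(defaults \(v_0 = 0.04\), \(d = 0.05\,\mathrm{yr}^{-1}\)), and
\(\varepsilon\) is Gaussian sensor noise (default sd 0.01 reflectance
units). This construction *builds in* the inverse texture–age relation:
within-stand spectral variance decays with age by design, so GLCM mean and
variance of the RED band decline as stands develop while mean infrared
reflectance rises.

Two geometry constraints matter. The analysis window (15 px) must fit
inside the image around every plot centre, and it should also fit inside
the *stand*: a window that straddles a stand edge mixes dark canopy with
bright background soil, and that edge contrast — largest for the oldest,
darkest stands — swamps and even reverses the internal-heterogeneity
signal. The default layout therefore uses stands at least as large as the
window. Users who deliberately want edge-contaminated windows can pass
their own `stand_layout`.

Stem communities follow the same saturating development curve: expected
large-stem counts and diameters grow with age (Gamma-distributed DBH above
the 5 cm census threshold), heights scale allometrically with DBH, and
species are drawn from a geometric rank-abundance series whose evenness
parameter increases with age. This yields increasing basal area, canopy
cover and richness and decreasing Simpson dominance along the
chronosequence — the qualitative trends of the bundled reference attribute
table — without attempting demographic realism. The generator makes no
claim to radiative-transfer realism, spatial autocorrelation of cover
beyond stand membership, crown-scale structure, or sun-view-angle effects;
passing tests demonstrate the *pipeline's* correctness and the
recoverability of planted relations, not performance on real imagery.

Endmember reflectances (bright soil: BLUE 0.12, RED 0.25, IR 0.30; canopy:
BLUE 0.04, RED 0.05, IR 0.45) are illustrative dry-season values chosen
once; no published calibration exists for the study system. All randomness
flows from a single integer seed, and identical configurations are
bit-identical.

## Layers and texture features

Four layers are analysed: raw RED and near-infrared reflectance, NDVI
\((\mathrm{IR} - \mathrm{RED})/(\mathrm{IR} + \mathrm{RED})\), and EVI
\(G (\mathrm{IR} - \mathrm{RED}) / (\mathrm{IR} + C_1 \mathrm{RED} -
C_2 \mathrm{BLUE} + L)\) with \(C_1 = 6\), \(C_2 = 7.5\), \(L = 1\) and
the standard gain \(G = 2.5\). The gain is not critical: texture is
computed after per-layer min–max quantization, so any fixed positive gain
leaves every GLCM feature unchanged (this invariance is tested). Pixels
with non-positive EVI denominators are masked rather than clipped so that
spurious extremes never enter the quantization; windows containing masked
pixels are skipped, not imputed.

Per plot and layer, ten statistics are computed over a 15×15 window
(≈ 39 m, matching a 30×30 m field plot): the data range and Fisher–Pearson
skewness of the raw values, and eight Haralick statistics — mean,
variance, correlation, contrast, dissimilarity, homogeneity, angular
second moment, entropy (natural log) — of the symmetric,
sum-to-one-normalized GLCM at distance 1, averaged over the four
directions 0°, 45°, 90°, 135°. Gray levels (default 64) are assigned from
the layer's *global* min–max range rather than per window, keeping levels
comparable across plots. GLCM correlation is undefined (flagged `NA`) for
zero-variance windows; candidate models containing such features are
excluded from selection. The implementation is verified cell-by-cell
against a brute-force pair-enumeration oracle and against scikit-image's
`graycomatrix`/`graycoprops` to 10⁻⁸.

## Stand attributes

Nested inventory sampling (large stems ≥ 5 cm DBH over 400 m², medium
2.5–5 cm over 200 m², small 1–2.5 cm over 100 m²) is scaled to one hectare
with expansion factors 25/50/100. Basal area uses
\(\pi (\mathrm{DBH}/200)^2\) per stem; crown area is the ellipse
\(\pi (d_1/2)(d_2/2)\) from the two orthogonal crown diameters (the
formula is the package's choice; only the measurements are standard).
Shannon \(H' = -\sum p_i \ln p_i\) and Simpson dominance
\(D' = \sum p_i^2\) use expansion-weighted abundance shares, consistent
with the per-hectare scaling (raw counts would over-weight small stems'
plots differently; the weighted choice is documented rather than claimed
canonical). \(D'\) is reported as dominance — 1 for a monoculture — which
the one-species forced cells of the reference table confirm. Mean canopy
height averages the tallest stem in each of the 8 zones formed by two
adjacent quadrats.

The upper-canopy set U — the stems a nadir sensor mostly sees — is
operationalized as the minimal prefix of stems, sorted by individual crown
area (ties: larger DBH, then input order), whose cumulative
expansion-weighted crown area reaches 50% of the plot total. A
median-crown-area rule is a defensible alternative reading of the
definition; the prefix rule is fixed here because it guarantees the U set
carries at least half the canopy cover, and all U ≤ T inequalities are
enforced and property-tested.

## Model search, nulls and cross-validation

Responses are log-transformed before fitting (`log-offset` with c = 1 is
auto-selected for attributes that can be zero, such as H' of a
single-species stand; a logit is available for D'). For each attribute and
each model size k ∈ {1, 2, 3} every predictor subset is fitted —
560 / 10,920 / 138,320 candidates over 40 features and 14 attributes —
and the largest-R² model is selected. The exhaustive path solves the
centered normal equations per subset (a 3×3 solve at most) and is verified
against `lm()`; ties within 10⁻¹² are broken by lower AICc, then
lexicographic predictor names. Model *sizes* are compared per attribute by
\(\mathrm{AICc} = n\ln(\mathrm{RSS}/n) + 2p + 2p(p+1)/(n-p-1)\) with
\(p = k + 2\) (slopes, intercept, error variance); sizes within 2 units of
the minimum are flagged equally supported.

Because the search screens thousands of models on ~15 plots, large R²
values arise by chance. The null model permutes the row order of the
entire feature table as a block relative to the response — preserving the
features' strong mutual collinearity, which an independent per-feature
shuffle would destroy — refits all candidates, and records the maximal R².
The empirical p is the strictly-greater fraction (so p = 0 is attainable),
and the null median summarizes the chance-expected R². With 199
replicates and the rejection rule p < 0.05, exchangeability of the
observed statistic among its permutations makes the test exactly
calibrated in expectation; the test suite measures the rejection rate at
5.2% over 500 simulations.

Predictive power uses leave-two-out cross-validation: all
\(\binom{n}{2}\) splits, refit on \(n-2\) plots, predict the held-out
two. The ranking criterion is the average validation sum of squares
(ASS); the summary statistic is

\[ R^2_{CV} = 1 - \frac{\sum (y_i - \hat y_i)^2}{\sum (y_i - \bar y)^2}, \]

with both sums pooled over all \(n(n-1)\) held-out predictions (each plot
is predicted \(n-1\) times). The pooling convention — rather than
per-split averaging — is fixed here so numerator and denominator are
commensurate; it reproduces 1 exactly on noiseless data and goes negative
for over-fitted models, both asserted to 10⁻¹⁰ in tests. Predictions and
\(R^2_{CV}\) are reported on the transformed (log) scale; back-transformed
predictions are positive by construction.

## Numerical choices and degenerate inputs

Quantization floors to integers with the maximum mapped to the top level;
constant layers map to level 0. Skewness of a constant window is defined
as 0. Constant-window GLCMs give contrast/dissimilarity/entropy 0,
homogeneity/ASM 1, and undefined correlation. Singular calibration designs
in cross-validation are excluded and counted rather than failing the run.
Rank-deficient candidate fits are flagged and never selected. Entropy uses
the natural log; any other base rescales it by a constant and cannot change
a selection made by R².

## Problem sizes used by the test suite

The suite runs the study-scale search (15 plots × 40 features, k ≤ 3,
all 149,800 candidates) in full, permutation calibration at 500 outer ×
199 inner replicates, sign recovery over 100 generated scenes, and
Monte-Carlo generator checks at 8–20 replicate seeds; the noise-degradation
property uses 3 noise levels × 8 seeds with the response planted on the
noise-free twin scene, isolating sensor noise as pure errors-in-variables.
These sizes are the package's own testing choices.

Two test-design notes deserve emphasis. First, texture features are
strongly collinear on realistic scenes (RED GLCM variance and contrast
correlate at ≈ 0.999), so "recover the planted predictor" is only
well-posed when the planted noise is small relative to that collinearity
gap; the recovery tests use noise at 1% of the signal's spread and verify
identity *and* sign of the selected predictor. Second, properties phrased
as trends over seeds (variance declining with age, basal area growing with
age) are asserted as large-majority outcomes (e.g. ≥ 18 of 20 seeds), not
certainties — the generator is stochastic by design.

## Known limitations

Scenes have no spatial autocorrelation of cover within stands, no shadows,
clouds, or view-angle effects, and stand geometry is rectangular; real
imagery will violate all of these. The reference chronosequence table
bundled with the package supplies realistic *response* distributions, but
the bundled analysis cannot reproduce the reference study's regression
coefficients because the original image and plot geolocations are not
available; headline numbers of that study reachable from in-package inputs
(candidate counts, the paired T-vs-U comparison, forced diversity cells)
are reproduced exactly and tested.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  scenario = scenario_config(ages = c(2, 5, 9, 13, 18, 25, 32, 42, 60)),
  k = 1:2, reps = 199, seed = 1
)
run <- run_pipeline(cfg)
subset(run$models, attribute == "BA_T")
subset(run$nulls, attribute == "BA_T")
```

The manifest written alongside the CSVs records the seed, window, gray
levels, candidate counts per model size and per-stage row counts; rerunning
with the same configuration reproduces every output byte for byte.
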