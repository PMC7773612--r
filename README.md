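# menirmap

Chemometric calibration and spatial mapping of tissue composition from
near-infrared (NIR) spectra.

## The problem

Diffuse-reflectance NIR spectroscopy probes overtone and combination
vibrations of O–H, C–H and N–H bonds, so the 1000–2500 nm spectrum of a
connective-tissue specimen carries information about its water, collagen
(measured through hydroxyproline, HP) and glycosaminoglycan (measured through
uronic acid, UA) content. Building a quantitative calibration from such
spectra involves a long chain of steps, each with choices that materially
affect the result:

1. **Preprocessing** — restricting to informative wavelength ranges, removing
   multiplicative/additive scatter (SNV, RNV or MSC), and Savitzky–Golay
   (SG) smoothing or differentiation, searched combinatorially over all
   range subsets × scatter methods × SG (window, polynomial, derivative)
   triples;
2. **Calibration** — single-response partial least squares regression fitted
   with the NIPALS algorithm, the component count chosen by Monte Carlo
   cross-validation (MCCV: repeated random 90/10 splits, validation RMSE
   averaged), and samples screened for outliers by Monte Carlo subsampling
   (75% fits, held-out residual statistics);
3. **Wavelength selection** — five algorithms compared against the base
   model: uninformative variable elimination (UVE), competitive adaptive
   reweighted sampling (CARS), random frog, moving-window PLS (MWPLS), and
   iteratively retaining informative variables (IRIV);
4. **Mapping** — assembling per-location predictions into the measurement
   lattice (9 × 14 for a meniscus sample), imputing unreachable edge cells
   as neighbour means, embedding the grid in a 20 × 20 canvas and bilinearly
   interpolating at spacing 0.01 to a 1901 × 1901 map, with
   measured-vs-predicted percent-error summaries.

`menirmap` implements this entire pipeline as a tested R package, for
spectroscopists and chemometricians who want each stage available as an
individually testable, seed-reproducible function. Because no public dataset
of human meniscus NIR spectra exists, the package ships a **synthetic phantom
generator**: Beer–Lambert mixtures of Gaussian constituent bands
(A(λ) = Σ_k c_k Σ_b a_b e^{−(λ−μ_b)²/2σ_b²}) with per-spectrum gain, offset
and baseline-slope scatter, channel noise, replicate structure, mass closure
(constituents are % of wet weight), and spatially smooth constituent fields
over the test lattice. Every claim the test suite makes is a claim about
this phantom.

## The model

For centred predictors X (samples × channels) and centred response y, NIPALS
PLS1 extracts components a = 1…A by

    w_a ∝ X'y,  |w_a| = 1;   t_a = X w_a;   p_a = X't_a / t_a't_a;
    q_a = y't_a / t_a't_a;   X ← X − t_a p_a';   y ← y − q_a t_a

and collapses to regression coefficients b = W (P'W)⁻¹ q, so that
ŷ = (X − x̄) b + ȳ. Components are chosen at the minimum of the MCCV error
curve; model quality is reported as Spearman ρ and RMSE of calibration,
cross-validation and prediction (RMSEC / RMSECV / RMSEP, in percentage
points, pp, or basis points, bp).

## Worked example

```r
library(menirmap)

sp <- phantomSpec(noiseSd = 2e-4)                      # low-noise phantom
ds <- generateDataset(sp, nTrainLocations = 115, seed = 1)
train <- averageReplicates(ds$train)                   # 345 spectra -> 115
train
#> SpectraSet: 115 spectra x 230 channels (1000.00-2499.95 nm, 1 segment)
#>   replicate groups: 115

cfg <- preprocessConfig(list(c(1060, 1172), c(1211, 1366), c(1560, 1840)),
                        scatter = "snv", sgWindow = 17, sgPolyOrder = 2,
                        sgDeriv = 0)
X <- spectraValues(applyPipeline(train, cfg))
y <- ds$trainRef$water

cv <- mccv(X, y, maxComp = 10, iterations = 200, seed = 1)
cv
#> CvCurve: 10 components evaluated, chosen n_comp = 4 (RMSECV 0.03375),
#>   200 iterations @ 90% train

model <- fitNipals(X, y, chosenComponents(cv))
preds <- predict(model, spectraValues(applyPipeline(ds$test, cfg)))
yte <- ds$testRef$water[ds$testRef$measured]
sprintf("rho_test = %.3f, RMSEP = %.3f pp", spearmanRho(yte, preds),
        rmse(yte, preds))
#> "rho_test = 0.998, RMSEP = 0.036 pp"

gm <- fillMissingNeighbors(assembleGrid(preds,
        cbind(ds$testRef$row, ds$testRef$col)[ds$testRef$measured, ]))
gm
#> GridMap 9x14: 55 measured, 71 imputed, 0 background
embedAndInterpolate(gm)
#> CanvasMap: canvas 20x20 -> interpolated 1901x1901 (spacing 0.01)
```

The MCCV curve picks 4 components (3 constituent degrees of freedom plus one
for the residual scatter structure); the held-out 55-location grid is
predicted with rank correlation 0.998 and an error of 0.036 pp — under 1% of
the water range, as expected at this noise level. The final
`CanvasMap` is the high-resolution constituent map.

The full orchestration — preprocessing grid search, outlier screening,
method comparison, mapping, manifest — is one call:

```r
res <- runPipeline(pipelineConfig(phantom = sp, seed = 1))
```

A thin CLI over the same functions lives in `inst/scripts/menirmap`
(subcommands `simulate`, `validate-config`, `run`).

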