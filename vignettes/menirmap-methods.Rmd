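---
title: "Methods: NIR calibration and constituent mapping in menirmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR calibration and constituent mapping in menirmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menirmap)
```

`menirmap` implements a complete diffuse-reflectance NIR chemometrics
pipeline — preprocessing search, NIPALS PLS1 calibration with Monte Carlo
cross-validation and outlier screening, five wavelength-selection
algorithms, and sparse-grid constituent mapping — together with the
synthetic phantom that makes all of it testable. This vignette documents
the models, the tunable parameters, the numerical choices, and what the
phantom does and does not establish about real data.

## The phantom generator

No public human-meniscus NIR dataset exists, so the package generates its
own study analog. A `phantomSpec()` describes:

* **Constituent ranges** (% of wet weight): water 70–75, hydroxyproline
  (collagen proxy) 20–22, uronic acid (glycosaminoglycan proxy) 0.6–0.8 —
  the literature composition of meniscus.
* **Band libraries**: 2–3 Gaussian absorbance bands per constituent, all
  centred inside 1060–1840 nm so the retained wavelength ranges keep
  signal. Water carries a band at 1440 nm — on the shoulder of its strong
  1400–1450 nm absorption — plus a secondary band at 1790 nm inside the
  third optical window; the uronic-acid bands have large per-unit
  amplitudes to compensate for sub-percent concentrations.
* **Mass closure**: constituents are percentages of wet weight, so the
  generator adds a residual dry-matter component at `100 − Σ constituents`
  with its own broad bands. Closure matters: SNV, RNV and MSC all remove
  per-spectrum scale, and without a closed mass balance absolute
  concentrations would be genuinely unidentifiable from scale-free spectra.
  With closure, shape encodes the absolute composition, which is exactly
  why these corrections work on real tissue.
* **Scatter and noise**: per-spectrum multiplicative gain `1 + N(0, 0.05)`,
  additive offset `N(0, 0.02)`, linear baseline slope `N(0, 2e-5)` per nm,
  and i.i.d. channel noise (default sd `1e-3` absorbance). These are
  precisely the distortion families SNV/RNV/MSC and SG differentiation are
  designed to remove, enabling end-to-end tests of the preprocessing.
* **Design**: 115 training locations × 3 replicates (replicates averaged
  into representative spectra before any preprocessing, since the
  representative spectrum is defined from raw acquisitions), and a 9 × 14
  test lattice of which 55 central cells are measured — the unmeasured
  cells are those farthest from the lattice centre, mimicking edge
  locations a probe cannot reach. Constituent fields on the lattice are
  spatially smoothed (moving-average kernel over an i.i.d. uniform field,
  rescaled into range) so maps are visually structured and every cell stays
  in range by construction.
* **Axis**: 1000–2500 nm at 6.55 nm spacing (230 channels).

What the phantom does **not** emulate: radiative-transfer photon physics,
instrument saturation, wavelength-dependent noise, reference-assay error in
the constituent values, and biological covariance between constituents
(fields are drawn independently). Passing tests therefore demonstrate that
the algorithms are implemented correctly and behave as designed under
band-structured, scatter-distorted spectra — not that any particular
performance level will be attained on real tissue.

## Preprocessing

Stages run crop → scatter correction → Savitzky–Golay, matching the usual
order in which excluded regions (noisy or saturated channels) are removed
before per-spectrum corrections:

* **Cropping** uses closed intervals (boundary channels included); segment
  boundaries are recorded so later filtering never crosses a gap.
* **SNV** is the per-spectrum z-score; **RNV** centres on the 25th
  percentile and scales by the sd of the channels at or below it, a
  convention from the originating robust-normal-variate literature (the
  percentile is exposed as a parameter); **MSC** regresses each spectrum on
  a reference and inverts the fit. The MSC reference is the *training-set*
  mean on the cropped axis, stored and reused for test spectra so no
  information leaks at prediction time.
* Scatter correction operates on the concatenated cropped channels, not per
  segment — scatter is a physical per-spectrum effect.
* **SG filtering** is applied per contiguous segment, with derivatives
  scaled by the channel spacing (units: intensity per nm^deriv). Edge
  channels are evaluated from the local polynomial fit so the channel count
  and axis alignment are preserved across configurations. Internally the
  filter is a precomputed dense matrix applied by one matrix product; it is
  verified channel-for-channel against `signal::sgolayfilt`.
* The **configuration enumerator** forms all non-empty subsets of the
  candidate ranges × scatter options ({none, SNV, RNV, MSC}; "none" is
  included because the original search space is not fully specified) ×
  valid SG triples (window ∈ {5,…,19}, polyorder ∈ {2,3}, deriv ≤
  polyorder), in a deterministic order used for tie-breaking.

## Calibration and model selection

NIPALS PLS1 mean-centres predictors and response but never variance-scales
— standard chemometrics practice for spectra, where channel variances carry
information. For a single response the NIPALS inner loop converges in one
pass, so no iteration tolerance exists. Weight vectors are unit-normalised;
coefficients collapse through `b = W (P'W)⁻¹ q`, and `P'W` is unit upper
triangular, so the solve is exact. Degenerate directions (residual
covariance below 1e-14) stop extraction early, which makes exact ties in
cross-validation resolve toward fewer components.

**MCCV** draws `round(0.9 n)` training samples per iteration (round-half-up:
90% of 115 is 104), fits once at the maximum component count, and scores
every count from that single decomposition. The chosen count is the global
minimum of the mean RMSECV curve, smallest count on ties; a
one-standard-error alternative is available via `oneSe = TRUE`. The grid
search evaluates every configuration on the *same* splits, so RMSECV
comparisons are paired and identical configurations tie exactly (broken by
serialization order).

**Outlier screening** records each sample's held-out absolute residuals
over repeated 75% fits. The flag rule is mean residual > cohort mean + 3 sd
(k configurable). The residual-spread axis is always reported but
contributes to flagging only when `axes = "both"`: its distribution is
heavy-tailed even on clean, exchangeable data, and including it by default
would dominate the false-flag rate. The rule itself is a design choice —
only the sampling scheme is fixed by convention.

## Wavelength selection

All five methods share the `SelectionResult` interface and are
seed-reproducible. Their fidelity target is the algorithmic skeleton of the
originating publications, validated by planted-signal recovery rather than
numeric identity to any particular implementation:

* **UVE** appends `n_channels` uniform noise channels of amplitude 1e-10
  (drawn under a seed derived from, not equal to, the user seed, so the
  noise can never duplicate a stream the caller used to build the data),
  collects coefficients over Monte Carlo refits, and keeps real channels
  whose |mean/sd| reliability exceeds the largest noise reliability.
* **CARS** follows the exponentially decreasing retention schedule solved
  from r₁ = 1 and r_N = 2/p, with forced selection by |coefficient| then
  adaptive reweighted sampling. Every iteration's subset is scored by
  paired-split RMSECV; among subsets within one standard error of the
  minimum, the smallest is returned (a parsimony rule in the spirit of the
  one-SE rule of cross-validated model selection).
* **Random frog** runs an accept/reject chain over subsets. Candidate sizes
  are drawn around the fixed anchor `initSize` (so the chain cannot drift
  into very large subsets where the error surface is flat); shrink moves
  keep the channels with the largest |coefficient| of a model fitted on the
  current subset, add moves are random. Acceptance is 1 for improvements
  and current/candidate error otherwise. Selection probability is visit
  frequency; by construction the probabilities sum to the mean visited
  subset size, which the tests assert as an accounting identity.
* **MWPLS** scores every contiguous window with paired-split RMSECV and
  returns the minimising window.
* **IRIV** samples balanced binary inclusion matrices (each surviving
  channel in half the rows; one split seed per round so row errors are
  paired), retains channels whose inclusion lowers the error — strongly
  informative when a Wilcoxon rank-sum test at α = 0.05 is significant,
  weakly otherwise — and removes the rest, iterating until stable or
  `maxRounds`, then backward-eliminates weak channels when removal improves
  RMSECV. On noisy data the "iterate until no removals" rule can erode
  genuinely informative channels one per round after the uninformative ones
  are gone; `maxRounds` exists to bound that erosion and is deliberately
  small (3) in the recovery benchmark.

### The planted-channel benchmark

Recovery is measured on `generatePlantedChannels()`: 200 samples, 220
channels, of which 20 contiguous channels are informative. Each informative
channel carries its *own* latent signal, and the response is the
band-profile-weighted sum of the latents (weights tapered only mildly,
0.9–1.2). This structure is deliberate: "retaining an informative channel"
is only a well-defined success criterion when each channel contributes
unique, comparable information. If the informative block were one shared
signal plus noise, any 3–5 channels would suffice and a selection algorithm
that drops the rest would be *right* to do so — redundancy makes retention
unmeasurable, not the algorithms wrong.

## Mapping

Predictions assemble into the 9 × 14 lattice by 0-based (row, col)
coordinates. Imputation is 4-connected neighbour-mean (8-connected behind a
flag), applied in sweeps where each sweep reads only the previous state —
so the result is order-independent — until no unmeasured cell borders a
valued cell; imputed values provably stay inside the measured range. The
filled grid is centred in a 20 × 20 zero canvas at offset
`floor((20 − dim)/2)` (5 rows, 3 columns for 9 × 14), and bilinearly
interpolated on the node lattice 1…20 at spacing 0.01, giving
(20 − 1)/0.01 + 1 = 1901 pixels per side. Because the nodes are regular,
bilinear interpolation is separable and is computed as `R %*% canvas %*%
t(R)` with `R` the 1-D linear interpolation operator — exact at nodes,
verified against a general bilinear oracle, and fast enough (tens of
milliseconds) for the 1901 × 1901 map. Background stays 0; masking it is a
rendering concern, the values are kept. Error maps report
`100·|pred − meas|/meas` over measured cells, excluding (and counting)
zero-valued cells.

## Pipeline, seeds, and problem sizes

`runPipeline()` derives one child seed per stage and constituent from the
master seed through a fixed affine map into the 32-bit range; reruns with
the same config are bit-identical, and the manifest records every child
seed. The default preprocessing grid in `pipelineConfig()` is a compact 168
configurations (all 7 range subsets × 4 scatter options × SG windows
{5, 11, 17}, polyorder 2, deriv {0, 1}): enough to exercise the search
while keeping a full three-constituent run around half a minute. The full
1344-configuration study grid is available via `enumerateConfigs()`
defaults. MCCV uses 1000 iterations by default in `mccv()` itself; the
pipeline and the test suite run 20–200 iterations, and outlier screening
100–250 rather than 2500 — these sizes were chosen as the package's own
benchmark conditions, with the Monte Carlo sd of the RMSECV scaling as
1/√iterations (asserted as a property test).

## Known limitations

* PLS1 only; constituents are modelled independently (no multi-response
  deflation, no closure constraint at prediction time).
* The outlier rule and the grid-search criterion (minimum RMSECV) are
  conventions; the underlying study context fixes only the sampling
  schemes.
* Selection hyperparameters (CARS runs, frog chain length, IRIV rounds) are
  conventional defaults; recovery rates are reported at the benchmark
  settings in `scripts/acceptance.R`.
* The phantom's independence of constituent fields and its Gaussian band
  model are idealisations; real spectra add baseline curvature,
  temperature-dependent band shifts, and reference-assay noise that the
  package does not simulate.
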