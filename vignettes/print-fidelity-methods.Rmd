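---
title: "Models and methods behind printfid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind printfid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(printfid)
```

printfid integrates four stages of an extrusion-bioprinting optimization
workflow — an analytic nozzle-flow model, image-based fidelity scoring, a
convolutional print-quality classifier, and factorial
design-of-experiments regression — together with synthetic-data
generators that make every stage testable without laboratory data. This
vignette documents the models, their assumptions, the tunable parameters,
and the design decisions taken where the methodology left choices open.

## The power-law extrusion model

Shear-thinning hydrogel inks are described by the Ostwald–de Waele
relation $\eta(\dot\gamma) = K \dot\gamma^{n-1}$, with flow-behavior
index $n$ (dimensionless; $n < 1$ means shear thinning) and consistency
index $K$ (Pa·s$^n$). `fit_power_law()` estimates both by ordinary least
squares in log–log space; the fit window defaults to the full measured
curve and is user-configurable, since instrument curves often include a
low-rate plateau one may wish to exclude.

The one-dimensional nozzle model chains five relations for a cylindrical
channel of radius $R$ and length $L$:

* volumetric flow $Q = V_{EXT}\,\pi R^2$;
* peak channel velocity $V_{MAX} = V_{EXT}\,(3n+1)/n$;
* the generalized Hagen–Poiseuille pair
  $V_{EXT} = \frac{n}{3n+1}\frac{R^2}{K}\frac{\Delta P}{L}$ and its exact
  algebraic inverse for $K$;
* the Newtonian pressure drop $\Delta P = 8\eta V_{EXT} L / R^2$;
* the deposited strand diameter
  $D_F = 4 W_N V_{EXT} / (n V_{MAX})$, which with the profile factor
  above reduces to $D_F = 4W_N/(3n+1)$.

Two readings deserve comment. First, the $(3n+1)/n$ velocity-profile
factor differs from the classical fully developed power-law pipe ratio
$(3n+1)/(n+1)$; the package implements the former as the default
(`profile = "astrid"`, after the source model's name) and offers the
classical form via `profile = "textbook"` so the two can be compared.
Second, $W_N$ in the diameter relation is dimensionally consistent only
as a length; it is therefore taken to be the nozzle inner *diameter*,
while the flow-rate relation uses the bore cross-sectional *area*. Both
choices are unit-checked in the test suite. At $n = 1$ the diameter
relation returns exactly the bore; for $n < 1$ it predicts a strand wider
than the bore, the familiar die-swell direction.

Public units are printer-native (mm, mm/s, kPa); the pressure-drop
relation is evaluated in SI internally, with all conversions in one
helper. The nozzle channel length is not printed on standard tips;
`nozzle_geometry()` defaults to 12.7 mm (a half-inch tip), records that a
default was used, and every report carries the flag. The gauge lookup
ships 25G = 0.250 mm and 27G = 0.210 mm and is overridable.

## Fidelity scoring

Printed meshes are photographed top-down and compared with the CAD
target. Preprocessing (`preprocess_image()`) follows the conventional
chain — grayscale, Gaussian smoothing ($\sigma$ = 1 px by default), global
threshold, resize — with two documented choices: the binarization
threshold is Otsu's method (the methodology named none), and the resize
target defaults to $128\times128$, the classifier's input size. The
physical scale is propagated through the resize so measurements stay in
mm.

Four scores are computed:

* **SSIM** (`ssim()`): windowed structural similarity with uniform
  $7\times7$ windows, sample-covariance normalization, and constants
  $C_1 = (0.01 D)^2$, $C_2 = (0.03 D)^2$ for dynamic range $D$. The
  methodology's printed formula has $(\mu_x^2+\mu_y^2+C_2)$ where the
  standard form has $(\sigma_x^2+\sigma_y^2+C_2)$; the standard form is
  the default because it preserves the identity $\mathrm{ssim}(x,x)=1$,
  and the literal variant remains available (`as_printed = TRUE`). The
  implementation agrees with scikit-image's reference to ten decimals on
  frozen fixtures.
* **Dimensional similarity**
  $S_D = 100 - \frac{|L-L_O|+|W-W_O|}{\max(L_O,W_O)}\cdot 100$. The
  source prints the length deviation without absolute bars; bars are
  applied to both axes so undershoot cannot push the score above 100.
* **Aggregate similarity** $S_A = (SSIM\% + S_D)/2$, with SSIM rescaled
  to percent before averaging.
* **Manual similarity** $100 - E_D$, where $E_D$ is the mean of the
  three percentage errors (length, width, strand diameter). The printed
  normalization multiplies the already-percentage errors by a further
  100; the implemented reading averages percentages (the literal formula
  is behind `literal = TRUE`).

All similarity outputs are clamped to $[0, 100]$.

`measure_mesh()` is the image-side analogue of caliper measurement:
length and width from the foreground bounding box, and strand diameter as
$2\,\mathrm{median}(d) - 1$ pixels, where $d$ are Euclidean
distance-transform values sampled on the Zhang–Suen skeleton. The $-1$
corrects the half-pixel offset of distances measured from pixel centers:
a strand exactly $w$ pixels wide has centerline distance $(w+1)/2$. The
median makes the estimate robust against the inflated distances at
strand crossings. `score_print()` measures at the image's native
resolution — the $128\times128$ resize is adequate for structural
comparison but too coarse for strand calipering.

## The print-quality classifier

`build_classifier()` constructs the binary CNN: input $128\times128\times1$,
four $3\times3$ convolution blocks with channel depths 32, 64, 128, 256,
each with batch normalization, ReLU and $2\times2$ max-pooling (leaving
an $8\times8$ map), a flatten, a 256-unit ReLU layer with L2 penalty, 50%
dropout, and a single sigmoid output (1 = High fidelity). The engine is
written in the package — im2col plus BLAS GEMM with compiled
gather/scatter kernels — and is exact: backpropagation is verified
against finite differences in the test suite. One structural note: a
convolution bias followed by batch normalization is mathematically
absorbed by the normalization's mean subtraction, so its gradient is
identically zero; the parameter is kept for architectural faithfulness
but never enters the computation.

Unstated training hyperparameters were fixed at conventional values and
are all recorded in the `training_config()`: Adam at $10^{-3}$, binary
cross-entropy, L2 coefficient $10^{-4}$, early stopping on validation
loss with best-weight restoration. Training follows the incremental
protocol: a stratified 80/20 split, then growing subsets of the training
partition (250 images, then +100 per stage) with the model carried
across stages. Class imbalance is handled by inverse-frequency loss
weights and, optionally, augmentation of the minority class restricted
to symmetry-preserving operations (flips and 90° rotations — a mesh
grid's symmetries). The High/Low label threshold on aggregate similarity
is not stated by the methodology; the package defaults to $S_A \ge 70\%$,
configurable and recorded with every dataset.

All randomness — split, initialization, shuffling, dropout, augmentation
— flows from the single seed in the configuration, making training
bit-reproducible.

`evaluate_classifier()` reports recall, F1 and accuracy at threshold 0.5,
ROC-AUC (via pROC), PR-AUC (average precision, integrated stepwise), and
per-class one-vs-rest AUCs. For a binary problem scored with
complementary probabilities the two per-class ROC-AUCs coincide
mathematically; they are reported separately from the overall value and
never conflated with it. `select_best_print()` takes the images predicted
High, ranks them by aggregate similarity (ties: manual similarity, then
lowest run id) and joins the winner to its row of the experiment matrix.

## Design of experiments

The full factorial design crosses nozzle gauge (27, 25 G), pressure
(160–200 kPa in 10 kPa steps) and velocity (5–25 mm/s in 5 mm/s steps):
50 cells; 17 replicates per cell give the 850-run scale used for
classifier data. Models are linear in the *centered natural-unit*
monomials $(A-26)$, $(B-180)$, $(C-15)$ and their products — not ±1
orthogonal coding — so fitted coefficients are directly comparable with
the shipped reference surfaces. `reference_model("eq19")` (filament
diameter, mm) and `reference_model("eq20")` (SSIM similarity, %) carry
the published coefficient sets with retained terms
$\{A, B, C, AB, AC\}$ and reported $R^2$ of 0.85 and 0.97; they are
literal reference objects, independent of any fitting, and double as
truth surfaces for the generator and as oracles for the fitting code.

`fit_factorial_model()` is ordinary least squares (via `lm()`) on all
seven monomials with per-term t-tests. Because the factors enter
numerically (8 parameters against 50+ runs), residual degrees of freedom
exist even at one replicate per cell, and every p-value is defined — a
saturated categorical coding would need replication, but that is not the
coding used here. `prune_model()` removes all non-intercept terms with
$p \ge \alpha$ (default 0.01) in a single pass and refits; no
hierarchical protection is applied, since the reference surfaces
themselves retain interactions whose parents the accompanying text calls
non-significant. One degenerate regime needs a rule: on noiseless
synthetic responses the residual variance is rounding error and
t-statistics are ratios of noise, so when the residual standard error
falls below $10^{-10}$ of the response scale the fit is classified as
exact and terms are kept or dropped by coefficient magnitude against a
$10^{-8}$ tolerance. With numeric coding, the two-level factor's centered
slope equals half the difference of its level means, and level means of
fitted values reproduce observed level means — both are verified against
brute-force cell-mean oracles in the tests.

The comparison statistics are MAE, MSE and the Pearson correlation. The
printed MSE formula references deviations from the mean rather than the
paired residual, which would make the statistic independent of the
predictions; the implemented MSE is the standard mean squared paired
residual.

## Synthetic data: what it emulates and what it does not

`render_mesh()` rasterizes an orthogonal strand grid (default: a
10 mm × 10 mm mesh of 5 × 5 strands, 0.25 mm wide — the 25G bore — at
0.05 mm/px in a 256 px field). Controlled imperfections mirror the
failure modes of real prints: a seeded fraction of strand segments
removed (segments span crossing to crossing, so a defect rate of 1
empties the image), an additive dimensional bias emulating over- or
under-extrusion, and Gaussian intensity noise. The ground truth
(length/width including bias, strand width) is returned with the image,
which is what makes measurement and scoring testable.

`generate_doe_responses()` adds Gaussian noise to a truth surface. When
no noise level is given it is derived in closed form from the surface's
reported $R^2$: over the fixed design,
$\sigma^2 = V_{truth}\,(1-R^2)/R^2$ with $V_{truth}$ the population
variance of the surface across the 50 cells, so a fit at the generated
noise reproduces the reported fit quality in expectation. This is a
calibration to the published summary statistic, chosen once; it is not a
claim about the original experiment's error structure.

`generate_labeled_dataset()` draws images from a two-component quality
mixture — good prints (defect rate below 5%, bias sd 0.1 mm) and bad
prints (30–60% broken segments, 1.5–3 mm bias) — scores each against the
CAD with the fidelity metrics, and labels them by the $S_A$ threshold.
The ground-truth dimensions stand in for caliper measurements. A
`plant_perfect` option renders one image exactly at CAD spec, planting a
known optimum for end-to-end selection tests.

What the generator does *not* emulate: microscope illumination and
focus, hydrogel translucency and die-swell texture, layer-stacking
artifacts, or correlated defects along a strand. Passing tests therefore
demonstrate that the algorithms are implemented correctly and behave
sensibly on data with known truth — not that the classifier's published
accuracy on real micrographs is reproduced, which would require the
original images.

## Problem sizes and numerical choices

The test suite exercises the classifier at two scales chosen by the
package: the full specified architecture on the 400-image, 128×128
problem for the acceptance properties (training converges on this
separable problem within two epochs per stage), and a reduced scale
(64×64 images, an 8/16-depth network) for training-behaviour properties
that need many training runs (seed stability, class weighting, data
scaling). The reduced scale keeps the image features that drive the
labels — broken strands and dimensional bias — at a quarter of the cost;
below 64 px the strand grid aliases away and good prints can no longer
be distinguished, so that is the floor.

Other numerical choices: Otsu thresholding on smoothed intensities;
SSIM window margins cropped before averaging so only fully valid windows
contribute; maxpool gradient routed to the first maximal element on
ties; probabilities clipped at $10^{-12}$ inside the cross-entropy;
similarity scores clamped to $[0, 100]$.

## Known limitations

* The extrusion model is one-dimensional and isothermal: no entrance
  effects, no temperature-dependent crosslinking on the bed, no
  cartridge-scale flow field.
* The filament-diameter relation inherits the printed profile factor; it
  is reproduced as stated, with the classical alternative available, and
  no claim is made that either matches a particular printer's die swell.
* Strand measurement assumes strands wide enough to rasterize (at least
  one pixel) and a predominantly orthogonal grid; heavily skewed or
  multi-layer geometries will bias the skeleton-based estimate.
* The classifier engine favours clarity and reproducibility over
  throughput; it trains the specified architecture on hundreds of
  images in minutes on one CPU, not on thousands of micrographs.
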