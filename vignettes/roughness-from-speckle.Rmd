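---
title: "Measuring nanoscale surface roughness from biospeckle texture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nanoscale surface roughness from biospeckle texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

When coherent laser light is backscattered from a biological surface, the
interfering wavelets form a speckle pattern whose texture carries
information about the surface topography. For articular cartilage, whose
earliest degeneration sign is a nanometre-scale roughening of the surface,
this offers a non-contact alternative to stylus profilometry: record a
speckle image, quantify its texture, and calibrate the texture statistics
against the arithmetic-mean roughness

$$R_a = \frac{1}{N}\sum_i |h_i - \bar h|,$$

the quantity a stylus profilometer reports (here in nanometres).

`speckleRa` implements this measurement chain end to end:

1. **Second-order texture**: symmetric, normalized gray-level co-occurrence
   matrices (GLCMs) $P_{d,\theta}$ at separation distances $d = 1\ldots10$
   px along $\theta \in \{0°, 45°, 90°, 135°\}$ — forty matrices per image
   at 256 gray levels.
2. **Haralick statistics**: eight scalar parameters per GLCM (ASM, CON,
   IDM, ENT, DA, DV, DE, CORR).
3. **Distance-curve asymptotes**: each parameter's curve versus $d$ is
   fitted with $y = y_0 + A e^{-Bd}$ and summarized by $y_0$ ($A$ and $B$
   track curve shape, not roughness, and are discarded).
4. **Feature table**: per image, $8 \times (4\times10 + 4) = 352$ features.
5. **Rating alignment and screening**: ASM, IDM and CORR rise with
   roughness while the rest fall, so those blocks are replaced by their
   reciprocals; the CORR block (44 columns) is then excluded — its values
   correlate weakly with everything else — leaving $p = 308$.
6. **Standardization and PCA**: columns are scaled to zero mean, unit
   variance; the covariance matrix $C = X^TX/(n-1)$ (which then equals the
   correlation matrix) is eigendecomposed; scores are $Y = XA$.
7. **Calibration**: because the 308 retained features are strongly
   mutually correlated, the first principal component absorbs almost all
   variance; its score is calibrated against $R_a$ with the same
   exponential law, $\mathrm{PC1} = y_0 + A e^{-B R_a}$, and inverted for
   prediction: $\hat R_a = -\ln\!\big((s - y_0)/A\big)/B$.

No public speckle image set with reference roughness labels exists, so the
package ships a speckle simulator that generates fully self-contained,
labelled data with the statistical structure the analysis assumes. The
simulator is first-class, tested code: it defines the study conditions
under which the package's claims are verified.

## The synthetic speckle model

### Surfaces

`generate_surface()` draws a white Gaussian height field, low-pass filters
it with a Gaussian kernel (standard deviation = the surface correlation
length, default 100 µm at a 25 µm grid pitch), recentres it and rescales to
the target $R_a$. Because $R_a$ is homogeneous of degree one in the
heights, the rescaling is exact rather than iterative; generated surfaces
hit their target exactly, well inside the 1 % contract.

### Rendering

`render_speckle()` is a phase-screen model. The illuminated spot is a
circular aperture; the reflected field carries the surface phase
$\phi = (4\pi/\lambda)\,h\cos\theta_{inc}$; the recorded image is the
centred squared magnitude of the 2-D discrete Fourier transform, quantized
to 8 bits. Three modelling choices deserve explanation:

**A diffuse phase screen is on by default.** With surface phase alone, a
surface with $R_a = 10$ nm at $\lambda = 632$ nm modulates the phase by
only ~0.24 rad, so ~94 % of the energy would sit in a specular spike and
the image would not be speckle at all. Real tissue does not behave like
that: volume backscatter from beneath the surface randomizes the optical
path at every roughness, which is why cartilage speckle is fully developed
even on optically smooth surfaces. The simulator represents this with a
single uniform random phase screen added to the surface phase — a one-line
stand-in for the qualitative effect of subsurface scattering, not a light
transport model. With it, speckle contrast is ≈ 1 at every $R_a$ and the
far-field grain size follows the $\delta_O = 1.22\lambda L/D$ aperture law
(the test suite checks both).

**Brightness falls with roughness through
$\exp(-R_a/R_0)$** (field amplitude; $R_0 = 2000$ nm): rougher surfaces
scatter more light out of the collection aperture, so their images darken.
The aperture energy is normalized out of the intensity, so $R_0$ alone
controls the darkening trend.

**Bright patches grow with roughness through the coherent spot.** The
coherently contributing spot shrinks as $D/(1 + R_a/R_1)$
($R_1 = 1500$ nm), which provably enlarges the far-field grain in
proportion to $(1 + R_a/R_1)$. An alternative — growing the *surface*
correlation length with $R_a$ — cannot deliver this trend once the phase
wraps: the field correlation length behaves like
$\ell_c(R_a)/\sigma_\phi(R_a)$ with $\sigma_\phi \propto R_a$, so the
linear growth cancels and the grain size is pinned by the aperture. Both
$R_0$ and $R_1$ are empirical knobs chosen to reproduce what rough-vs-
smooth tissue images show (darker, larger-patched images at high $R_a$);
they are configurable and carry no physical derivation.

**Quantization** maps the 99th intensity percentile of the *smoothest*
image of a batch to gray level 250 and applies that same scale to the whole
batch (clip at 255, round half-up). Anchoring one common scale preserves
the cross-image brightness ordering that the analysis exploits; absolute
gray levels remain comparable across a batch.

### What the simulator does and does not emulate

It reproduces: fully developed speckle grain structure with aperture-scaled
grain size; mean gray level decreasing and bright-patch area increasing
with $R_a$; GLCM mass concentrating toward the principal diagonal with
increasing $R_a$; and, downstream, strongly correlated texture features
with a single dominant principal component and an exponential PC1-vs-$R_a$
relationship.

It does not emulate: tissue light transport, polarization, the subjective
(lens) imaging chain, camera noise beyond quantization, or specimen
heterogeneity. Passing tests therefore demonstrate that the *analysis
chain* behaves as designed on data with the assumed statistical structure —
they are not evidence about any particular tissue, and a real deployment
still requires its own profilometer-labelled calibration set.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `wavelength` | 632 | nm | He-Ne laser line |
| `spot_diameter` | 4 | mm | illuminated spot; sets grain size via Eq. above |
| `propagation_distance` | 50 | cm | camera distance |
| `incidence_angle` | 15 | deg | beam-to-normal angle; scales the surface phase |
| `attenuation_scale` $R_0$ | 2000 | nm | darkening rate with roughness |
| `patch_growth_scale` $R_1$ | 1500 | nm | bright-patch growth with roughness |
| `pixel_pitch` | 25 | µm | surface grid pitch; the implied camera pixel $\lambda L/(N\,\Delta x) = 31.6$ µm samples one grain with ~3 px |
| `correlation_length` | 100 | µm | surface correlation (Gaussian kernel SD) |
| `distance`, `direction`, `levels` | 1–10, four, 256 | — | GLCM grid for 8-bit images |
| selection `threshold` | 0.8 | — | conventional boundary of a "strong" correlation |

The default roughness grid for simulated datasets is twelve log-spaced
values over 10–2500 nm: the range relevant to early cartilage degeneration,
spanning more than two decades so the exponential calibration is well
constrained.

## Numerical choices

- **GLCM offsets.** Directions are interpreted in image-axis (row, col)
  coordinates: 0° → (0, +d), 45° → (−d, +d), 90° → (−d, 0),
  135° → (−d, −d). Whether the two diagonals follow image or Cartesian axes
  is a pure labelling choice; swapping them only permutes the two diagonal
  feature blocks. Out-of-image neighbours are skipped (no padding); counts
  are integers, normalization happens once in floating point.
- **Entropies** use the natural logarithm ($0\log 0 := 0$); the base is
  configurable and only rescales ENT/DE, which standardization removes.
- **DE** is computed from the difference marginal $P_{x-y}(k)$, consistent
  with the DA and DV definitions.
- **CORR** divides by the product of marginal standard deviations; when a
  marginal spread is zero (e.g. a constant image) CORR is `NA` —
  propagated as missing, never silently zero. $\sigma_x, \sigma_y$ are
  standard deviations (square roots of the marginal variances); only then
  is CORR confined to $[-1, 1]$.
- **Exponential fits** run Levenberg–Marquardt from several starts ($y_0$
  from the last point, $A$ from the first, $B$ from a log-linear
  regression plus a grid of rates scaled to the x-range), backed by a
  profile scan: for fixed $B$ the model is linear in $(y_0, A)$, so a
  50-point log-spaced grid over $B$ always yields a valid least-squares
  solution even where the full nonlinear iteration diverges. The best
  solution by residual sum of squares wins. A constant response
  short-circuits to $y_0$ = that constant, $A = 0$, $R^2 = 1$ by
  convention. $B$ is constrained positive.
- **Correlation matrix** uses sample ($n-1$) denominators throughout; the
  self-correlation diagonal is set to exactly 1.
- **Eigendecomposition** uses the symmetric eigensolver; eigenvector signs
  are fixed so each column's entry sum is non-negative (ties: first
  nonzero entry positive). Signs are otherwise arbitrary; this convention
  makes the all-positive first component report as such. Eigenvalues below
  $10^{-10}\lambda_{max}$ count as zero, which is what "eleven live
  components from twelve observations" means.
- **Extrapolation** in prediction is flagged (score or inverted $R_a$
  outside the calibrated range, with a $10^{-8}$ relative guard against
  boundary rounding), never refused; scores slightly above the $R_a = 0$
  point of the curve invert to slightly negative values and come back
  flagged.
- **Model serialization** writes doubles with 17 significant digits so a
  saved pipeline predicts bit-identically after reloading.

## Open design points, resolved

- The paper-style screening excluded the correlation block by inspection;
  the package automates it as *block-granularity* screening (median
  absolute out-of-block correlation below threshold drops the block) and
  also offers an explicit-list mode, which is the default used by the
  trained pipeline.
- Prediction for unseen images is not defined by the original analysis;
  the package completes it in the only self-consistent way — replay the
  frozen feature configuration, reciprocal blocks, retained columns and
  standardization constants, project on the stored first eigenvector, and
  invert the calibration curve.
- Calibration RMSE is reported in PC1-score units.
- Raw PC1 scores (not rescaled by the component spectrum) enter the
  calibration.
- Monotone-trend checks (mean gray, bright-patch area, GLCM diagonal
  concentration, Haralick trends) are evaluated on seed-set averages (five
  master seeds): at the smooth end of the grid the roughness-driven
  differences are a few percent, below single-draw noise.

## Problem sizes

The test suite and the acceptance script run the full study conditions —
twelve 400×400 images, forty 256×256 GLCMs each, 352 features, a 308×308
eigenproblem — in about two minutes on one core; training the pipeline on
one dataset takes ~12 s. Smaller grids (96×96, six images) back the
plumbing tests.

## Worked example

```{r example}
library(speckleRa)

dataset <- simulate_speckle_dataset(seed = 42)   # 12 labelled images
pipeline <- train_roughness_pipeline(dataset)
glance(pipeline)

held_out <- simulate_speckle_dataset(seed = 99)  # fresh noise, same grid
predict(pipeline, held_out)

autoplot(pipeline$calibration)
```

## Known limitations

- The $(R_0, R_1)$ couplings are tuning knobs reproducing empirical
  trends, not physics; no quantitative roughness–decorrelation law for
  cartilage is available to anchor them.
- With the diffuse screen on, the roughness signature in the image
  statistics is carried by those couplings; the surface phase contributes
  path-length detail but little statistical contrast between roughness
  levels.
- Specimen-specific quantities from any particular tissue experiment
  (exact component percentages beyond the first, standardized feature
  ranges) are not reproducible without that experiment's images; the
  package verifies structural counts, analytic identities, and the
  synthetic-data reproduction of the qualitative and threshold claims.
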