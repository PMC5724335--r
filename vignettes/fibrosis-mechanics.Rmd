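---
title: "Quantifying diffuse myocardial fibrosis and LV mechanics: models and methods"
author: "fibromech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying diffuse myocardial fibrosis and LV mechanics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibromech)
```

## The problem

Diffuse myocardial fibrosis — an expansion of the extracellular matrix that
is invisible to late-gadolinium enhancement — can be quantified in vivo from
inversion-recovery T1 mapping before and after gadolinium contrast.
Ventricular mechanics (strains, strain rates, contraction dyssynchrony) can
be quantified from displacement-encoded (DENSE) cine MRI acquired at the
same short-axis positions. `fibromech` implements both quantification
chains and the statistical machinery to relate them across a cohort with
repeated (regional or segmental) measures per subject. Because patient
images cannot ship with a package, every stage is paired with an analytic
phantom generator whose ground truth is known in closed form; the test
suite and the acceptance script exercise the chains against those closed
forms.

## Fibrosis from T1 mapping

### Signal model and T1 fitting

A magnitude inversion-recovery series is modelled per pixel as

$$ S(TI) = \left| A - B\, e^{-TI/T_1^*} \right| $$

with the Look-Locker correction $T_1 = T_1^*\,(B/A - 1)$. Magnitude
reconstruction discards polarity, so `fit_t1()` restores it by trying
candidate null-crossing positions around the minimum-magnitude sample and
keeping the lowest-residual fit. For fixed $T_1^*$ the model is linear in
$(A, B)$, so the fit is solved by variable projection: a coarse log-spaced
grid over $T_1^*$ followed by local refinement of *every* polarity
candidate, with the candidate chosen after refinement. This avoids
nonlinear-optimizer starting-value failures entirely; on noiseless
phantoms the recovery is exact to the optimizer tolerance (relative errors
below $10^{-3}$ %), and at a signal-to-noise ratio of 50 the mean bias is
below 0.2 % of the true T1. Estimates outside (1, 5000) ms mark the pixel
invalid rather than raising, since stray pixels must not abort a map fit.

### ROI policy

T1 at tissue interfaces is contaminated by partial-volume averaging with
blood and lung, so the myocardial ROI is restricted to the mid-wall:
`extract_midwall_roi()` removes a configurable wall-thickness fraction
(default 0.25 per side) at both the endocardial and epicardial borders.
The rule is parameterized as a fraction because the clinical papers state
the intent, not a rule; 25 % per side retains the middle half of the wall.
Contours are treated as star-shaped about the endocardial centroid — true
for LV short-axis slices — and a pixel belongs to the ROI iff its center
lies inside the eroded annulus (center-in-polygon rule, no interpolated
contour strips).

The 16-segment partition (`partition_segments()`) anchors equal angular
sectors at the manually marked anterior RV insertion point: 6 sectors of
60° on basal and mid slices, 4 of 90° apically, numbered 1–6 / 7–12 /
13–16 proceeding counterclockwise as viewed from the apex, segment 1
anterior. The angular direction and the anterior start are conventions the
package fixes explicitly since output tables are meaningless without them.

### Partition coefficient, synthetic hematocrit, ECV

With scope-level (slice or segment) mean T1s, the gadolinium partition
coefficient is

$$ \lambda_{Gd} = \frac{1/T_{1,myo}^{post} - 1/T_{1,myo}^{pre}}
   {1/T_{1,blood}^{post} - 1/T_{1,blood}^{pre}} , $$

which is dimensionless and invariant to common unit rescaling (ms ↔ s) —
a property the tests verify numerically. `summarize_fibrosis()` computes
$\lambda$ from scope-mean T1s rather than averaging per-pixel $\lambda$
values: this matches ROI-based clinical practice, and the ratio of means is
far more robust to per-pixel outliers than the mean of ratios. (On
homogeneous tissue both conventions agree exactly; on real maps they can
differ, which is why the choice is documented here and in the output
metadata.)

When a measured hematocrit is unavailable, it is estimated from the native
blood T1 via the linear relationship $Hct = a/T_1 + b$. The coefficients
live in configuration (`hematocrit_coefficients()`, defaults
$a = 866.0$ ms, $b = -0.1232$ from a published 1.5 T validation) and are
deliberately never hard-coded in computation paths: a site with its own
calibration replaces them without touching code. Estimates outside
(0.1, 0.65) are flagged implausible but still returned, so the caller sees
the data rather than a hole. Finally

$$ ECV = \lambda_{Gd}\,(1 - Hct). $$

Scopes with fewer than 10 valid pixels are excluded from downstream
tables; ECV outside [0, 1] is kept but flagged.

## Mechanics from displacement encoding

### Phase to displacement

DENSE encodes tissue displacement since a reference instant into pixel
phase: $\phi = 2\pi k_e u$ per in-plane axis, with encoding frequency
$k_e$ (0.10 cycles/mm in the emulated protocol, i.e. one phase wrap per
10 mm of motion). Displacements beyond half an encoding period alias, so
`phase_to_displacement()` unwraps each frame with a quality-guided
region-growing algorithm (compiled code; quality is magnitude weighted by
local wrapped-gradient coherence, so growth proceeds through reliable
tissue before approaching noisy boundaries). Spatial unwrapping leaves one
$2\pi k$ ambiguity per connected component; it is resolved temporally, by
matching each frame's solution to the previous frame's (the first frame,
acquired immediately after encoding, is referenced to zero). The phantom
generator warns when a requested deformation steps by more than half an
encoding period between frames or adjacent pixels, because no unwrapping
strategy can traverse such a step.

### Trajectories

The displacement measured at a pixel is Eulerian — it belongs to the
tissue currently there. `build_trajectories()` converts to material
(Lagrangian) trajectories by fixed-point iteration of $x = X_0 + u(x)$
per frame with bilinear interpolation, warm-started from the previous
frame. Two smoothing steps precede and follow: spatially, each frame's
field is smoothed by a Gaussian-weighted *local plane fit* (default
$\sigma$ = 1 pixel). A plane fit rather than a weighted mean matters at
mask edges: a kernel clipped by the mask biases a weighted mean of any
non-constant field, and that bias masquerades as strain; a local-linear
fit is exact for affine fields (hence for all rigid motions) regardless of
how the support is clipped. Temporally, each point's displacement history
is fit by a least-squares polynomial (default order 5, capped at
$n_{frames}-2$; an interpolating order is rejected because it would not
smooth at all). Points whose position leaves the valid field of view are
invalid from the first exit frame onward.

### Strain

For each element (one per reference myocardial pixel) the local
deformation gradient $F$ is estimated per frame by least squares over the
element's reference neighborhood (default radius 2.5 pixels, at least 6
valid neighbors), and the Green–Lagrange tensor

$$ E = \tfrac12\,(F^{\mathsf T} F - I) $$

is projected onto radial and circumferential unit vectors defined at the
reference configuration relative to the LV centroid. The Green–Lagrange
measure is chosen for objectivity: it vanishes identically under rigid
motion, where a small-strain (linearized) tensor would report spurious
strain under the rotations a beating heart actually performs. The tests
verify machine-zero strain on analytic rigid trajectories and < 1 %
absolute RMS recovery against closed forms through the full imaging chain
(isotropic scaling $r = kR$ gives $E_{cc} = E_{rr} = (k^2-1)/2$; the
area-preserving annulus $r^2 = R^2 + d$ gives $E_{cc}(R) = d/(2R^2)$).
Reported strains are the tensor projections × 100 (percent). Only
elements tracked over the whole cine enter the strain analysis:
trajectories with truncated temporal support carry a different
polynomial-fit residual than their neighbors, which would register as
artificial strain gradients.

Strain rates are centered finite differences of the slice-mean
circumferential strain curve, in %/s; peak circumferential strain is the
signed minimum, peak radial strain the maximum, systolic/diastolic strain
rate the signed minimum/maximum of the rate curve. Segmental peak strains
are exported; segmental strain rates deliberately are not (their
reproducibility is undemonstrated, and only regional/global rates enter
the statistical tables).

### Contraction delays and the dyssynchrony index

Each element's circumferential strain curve is compared against a
subject-level reference curve — the mean over all valid elements across
all available slices — by normalized cross-correlation over integer frame
lags within ±⅓ of the cine duration, with parabolic interpolation around
the discrete peak for sub-frame resolution. Curves are mean-removed and
amplitude-normalized before correlation, so delay estimation responds to
timing, not to strain magnitude differences between elements. Per-segment
delay is the mean of element delays. The delay search window is a design
choice (no window is standard); ±⅓ of the cine comfortably covers
physiologic delays while excluding degenerate end-overlap lags.

The dyssynchrony index smooths the segmental delays circumferentially
with a periodic cubic spline interpolant over angular position, evaluates
it on a dense 360-point grid, and takes the standard deviation of the
smoothed values — in population form (divisor $n$), because the quantity
is a descriptive statistic of a fully observed smoothed curve, not an
inference from a sample. (Reproducibility statistics below use the sample
form, where inference on differences is the point; the two conventions
are deliberate and recorded in the output metadata.) DI is non-negative
and invariant to a uniform additive delay, both verified by tests. Because
the reference curve is ventricular, subjects missing a slice receive no DI
at all: their delay table is emitted with an incomplete flag, and the
pipeline logs the exclusion while keeping their strain measures.

## Cohort statistics

### Standardization and mixed models

Analysis variables are prepared per outcome: natural-log transform where
the outcome's distribution requires it (the dyssynchrony index and the
diastolic strain rate in the emulated study), applied *before* z-scoring;
outcome, predictor and age are z-scored against the analysis sample's own
mean and SD; sex enters as an unstandardized binary indicator. Whether
age and sex should also be standardized is genuinely ambiguous in the
source conventions; standardizing age and leaving the binary indicator
raw makes every continuous coefficient a per-SD effect while keeping the
sex contrast interpretable.

`fit_mixed_model()` fits a *marginal* linear model by generalized least
squares (REML) with fixed effects {predictor, age, sex, level} and a
within-subject residual correlation structure: fully unstructured (3×3)
for the regional analysis, exchangeable (compound-symmetric) for the
segmental one. The marginal formulation is chosen over a random-intercept
parameterization because an unstructured correlation matrix is exactly
representable in it, and compound symmetry is recovered as the
exchangeable special case. A singular or non-convergent unstructured fit
falls back to exchangeable with an explicit `downgraded` flag. The
reported coefficient is the standardized predictor effect with a Wald
p-value on $n_{obs} - n_{fixed}$ residual degrees of freedom — a
deliberate, documented choice, since no degrees-of-freedom method is
canonical for GLS coefficient tests.

The cohort simulator (`generate_cohort()`) draws from exactly this model:
standardized predictor with exchangeable within-subject correlation,
centred level offsets, age/sex effects, and residuals with either an
arbitrary user-supplied 3×3 correlation (default a heterogeneous AR-like
matrix — basal/mid 0.6, mid/apical 0.7, basal/apical 0.45 — since no
empirical unstructured values are available to copy) or an exchangeable
coefficient (default 0.5). With `residual_sd = "auto"` the residual scale
is set so the marginal outcome variance is 1; the injected standardized
coefficient is then directly the quantity the analysis recovers after
sample z-scoring, which is what makes parameter-recovery testing sharp.
Simulating 40 subjects × 3 regions with injected coefficients of 0.67
(log outcome) and −0.36 (identity) and refitting over 200 replicates
recovers the truth within two Monte-Carlo standard errors, and the type-I
error at a zero coefficient stays in [0.03, 0.08] over 500 replicates —
both checks run in the test suite at exactly these sizes.

### Multiplicity, correlations, reproducibility, power

* `bh_adjust()` implements the Benjamini–Hochberg step-up rule within an
  outcome's family of predictor tests; a property test matches it against
  brute-force enumeration on 1000 random p-vectors.
* `pearson_with_p()` gives the exact t-based two-sided test of zero
  correlation on $n-2$ df.
* `mean_cov()` implements the paired-observation mean coefficient of
  variation $\sum_i SD(x_{1i},x_{2i}) / |\sum_i \bar x_i|$ (per-case SD of
  two observations, $|x_1-x_2|/\sqrt2$), and `bland_altman()` the bias
  ± 1.96·SD limits of agreement with sample-form SD.
* `zscore_against_reference()` looks reference means/SDs up from a
  user-supplied table keyed by measure and sex; reference-population
  constants are configuration, never package truth.
* `min_n_correlation()` returns the smallest n at which the two-sided
  test of zero correlation reaches a target power at true correlation
  $\rho$. Exact power uses the representation of the test statistic as
  noncentral t conditional on the predictor sum of squares
  ($S \sim \chi^2_{n-1}$, noncentrality $\rho\sqrt S/\sqrt{1-\rho^2}$),
  integrated numerically — for $\rho = 0.30$, $\alpha = 0.05$, power 0.80
  this gives $n = 84$ (power 0.8003 at 84, 0.7955 at 83). The Fisher-z
  approximate mode (available, and labelled in the result) gives 85; the
  two modes genuinely differ at this effect size, which is why the exact
  mode is the default.

## What the phantoms do and do not emulate

The generators produce: magnitude inversion-recovery series with known
per-tissue T1, polarity loss and Gaussian noise; Eulerian
displacement-encoded phase/magnitude cines of an annulus deforming under
analytic laws (rigid translation/rotation, isotropic scaling,
area-preserving radial motion) with per-sector activation delays blended
linearly over a 10° transition so the displacement field stays continuous;
and long-format cohort tables with known standardized effects. They do
*not* emulate off-resonance, motion artifacts, T2* decay, through-plane
motion, view-sharing reconstruction, CSPAMM echo suppression, realistic
myocardial fiber architecture, or RV geometry. Passing tests therefore
demonstrate that the algorithms are correct on data obeying their stated
models — not that the package compensates scanner-specific artifacts.
Sector delays are restricted to radial deformation laws because a
sector-wise delayed rigid motion has no single-valued inverse and could
not be imaged consistently even in principle.

## Numerical choices and problem sizes

Degenerate inputs fail loudly and specifically: empty post-erosion masks
name the slice; non-positive outcomes under a log policy name the record;
a vanishing blood relaxation-rate change (|denominator| < 1e-9 /ms) raises
a contrast-dynamics error rather than returning an unbounded $\lambda$.
Ties in the polarity search resolve by lowest residual after refinement.
The cross-correlation's parabolic refinement is clamped to ±half a frame
to keep the sub-frame correction local.

The test suite runs its phantom recoveries at 96²–128² grids with 11–15
frames and its Monte-Carlo statistics at 200–500 replicates of 40 × 3
cohorts; these sizes were chosen as the smallest at which discretization
error sits well inside the tested tolerances, and they keep the full
suite close to two minutes.

## Known limitations

* Strain is 2D in-plane; longitudinal strain and through-plane motion are
  out of scope.
* The unwrapper has no residue-balancing branch-cut stage; pathological
  phase topologies that defeat quality-guided growth are flagged by the
  feasibility warning rather than repaired.
* The GLS Wald test with residual degrees of freedom is mildly liberal in
  small samples (type-I error nearer 0.06 than 0.05 at 40 subjects), which
  is visible — and bounded — in the calibration test.
* The synthetic-hematocrit relationship is a population calibration; its
  defaults travel with the configuration and should be replaced by a
  site-specific fit where one exists.

## A worked run

```{r, eval = FALSE}
cfg <- validate_config(list(
  outdir = tempfile("fm-demo-"),
  simulate = list(n_subjects = 6L, missing_slice_subjects = 1L)))
res <- run_pipeline(cfg)
head(res$fibrosis[res$fibrosis$scope == "slice", ])
res$mechanics
res$models
res$exclusions
```

The run writes `fibrosis.csv`, `mechanics.csv`, `models.csv`,
`exclusions.csv` and `run.log` to `cfg$outdir`; reruns with an identical
configuration are byte-identical.
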