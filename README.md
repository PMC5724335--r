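# fibromech

Quantification of **diffuse myocardial fibrosis** from inversion-recovery
(MOLLI-style) T1 mapping and of **left-ventricular mechanics** from
displacement-encoded (DENSE) cine MRI, with standardized linear mixed
models relating the two across a cohort with repeated regional or
segmental measures per subject.

The package is aimed at cardiac MR researchers who need a tested, scripted
version of this analysis chain — and at method developers, who get analytic
phantom generators with closed-form ground truth for every stage.

## What it computes

**Fibrosis (T1 chain).** Per-pixel T1 from the three-parameter magnitude
inversion-recovery model S(TI) = |A − B·exp(−TI/T1\*)| with polarity
restoration and Look-Locker correction T1 = T1\*(B/A − 1); mid-wall ROI
restriction; the standard 16-segment partition anchored at the anterior RV
insertion point; and, from scope-level mean T1s,

    λ_Gd = (1/T1_myo_post − 1/T1_myo_pre) / (1/T1_blood_post − 1/T1_blood_pre)
    Hct  = a / T1_blood_native + b        (synthetic hematocrit, configurable a, b)
    ECV  = λ_Gd · (1 − Hct)

**Mechanics (DENSE chain).** Quality-guided 2D phase unwrapping with
temporal seeding; displacement u = φ/(2π·k_e); material-point trajectories
(spatial local-plane smoothing + temporal polynomial fitting); local
deformation gradients and the Green–Lagrange tensor E = (FᵀF − I)/2
projected onto radial/circumferential directions; peak strains and
circumferential strain rates; cross-correlation contraction delays with
sub-frame (parabolic) resolution; and the dyssynchrony index DI = the
standard deviation of periodic-spline-smoothed segmental delays.

**Statistics.** Standardized marginal mixed models (GLS/REML) with
unstructured (regional) or compound-symmetric (segmental) within-subject
correlation; Benjamini–Hochberg step-up flags per outcome family; Pearson
correlations with exact t-tests; z-scores against configurable reference
populations; mean coefficient of variation and Bland–Altman limits of
agreement for observer reproducibility; and exact power analysis for
correlation tests.

**Phantoms.** Inversion-recovery, displacement-encoded, and cohort
simulators with known ground truth (`generate_molli_phantom()`,
`generate_dense_phantom()`, `generate_cohort()`), driving both the test
suite and the end-to-end synthetic pipeline (`run_pipeline()`).

## Worked example

```r
library(fibromech)

## fibrosis measures from ROI-mean T1s (ms)
lam <- compute_lambda_gd(t1_myo_pre = 950, t1_myo_post = 414,
                         t1_blood_pre = 1550, t1_blood_post = 300)
hct <- synthetic_hematocrit(1550)
ecv <- compute_ecv(lam, hct)
#> lambda_Gd = 0.507, synthetic Hct = 0.436, ECV = 0.286

## mechanics from a displacement-encoded phantom with a contracting
## annulus and a 30 ms activation delay injected into sectors 4-6
sp <- dense_phantom_spec(grid_size = 96, n_frames = 15,
  deformation_law = list(type = "incompressible-annulus", delta = -120),
  segment_delays = c(0, 0, 0, 30, 30, 30))
ph <- generate_dense_phantom(sp)
fld <- phase_to_displacement(ph$phase_x, ph$phase_y, ph$magnitude,
  encoding_frequency = ph$encoding_frequency,
  frame_times = ph$frame_times, pixel_spacing = ph$pixel_spacing)
tr <- build_trajectories(fld, ph$mask_ref)
sc <- compute_strains(tr, ph$lv_center)
peak_metrics(sc)
#> peak Ecc = -6.4%, peak Err = 7.4%, systolic SR = -46 %/s, diastolic SR = 49 %/s
dl <- segmental_delays(sc)
dyssynchrony_summary(dl)$per_slice
#> segment delays (ms): -13.2, -14.5, -13.3, 13.1, 14.4, 13.1
#> DI = 13.3 ms

## sample size for detecting r = 0.30 at 80% power (exact)
min_n_correlation(rho = 0.30, alpha = 0.05, power = 0.80)
#> 84
```

The delayed sectors sit one frame (≈ 26–29 ms) after the synchronous ones,
and the DI matches the same spline-then-SD statistic applied to the true
injected delays to within 2 ms. The end-to-end synthetic study —
paired T1 and displacement-encoded phantoms per subject, both chains, and
the mixed-model association stage with exclusion accounting — runs with
`run_pipeline()` (see the methods vignette), or from a shell via the
wrapper in `inst/exec/fibromech`.

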