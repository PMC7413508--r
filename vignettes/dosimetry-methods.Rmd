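---
title: "Methods: voxel and organ-level dosimetry, and how the pieces fit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel and organ-level dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxdose)
```

# Scope and model overview

`voxdose` implements the two deterministic calculation routes of internal
dosimetry for ¹⁷⁷Lu radionuclide therapy and the statistical layer used to
compare dosimetry methods against each other (including against Monte
Carlo results, which enter only as externally computed dose tables):

1. **Organ-level MIRD dosimetry**: a single mean absorbed dose per organ,
   $D_t = \sum_s \tilde{A}_s\, S(t \leftarrow s)$, from a user-supplied
   S-factor table, with reference-mass scaling of the self-dose term, and
   a unit-density sphere model for lesions and phantom inserts.
2. **Voxel-level kernel convolution**: a 3D dose map
   $D_i = \sum_j \tilde{A}_j\, k(i-j)$ from a per-voxel time-integrated
   activity (TIA) map and a voxel S-value kernel.

Both routes consume the same TIA machinery, and both are exercised end to
end on synthetic voxel phantoms so that every claim in the test suite is
checkable without clinical images. SPECT projection/reconstruction,
attenuation and scatter modelling, image registration, partial-volume
correction and Monte Carlo transport are out of scope; registration is
assumed done upstream (all images of a series must share one grid).

# Time-integrated activity

Organ and voxel TIA follow one rule: trapezoidal integration between the
first and the last acquisition, analytic integration outside that window.

* **Tail** (beyond the last scan): $A(t_N)/\lambda$, where $\lambda$ is
  either the physical decay constant (`tailMode = "physical"`, the phantom
  workflow, where the only kinetics is radioactive decay) or the terminal
  rate of a fitted decay model (`tailMode = "effective"`, the patient
  workflow).
* **Head** (before the first scan at $t_1$): the published workflows do
  not state a convention, so it is a selectable parameter. The default is
  a triangle from $(0, 0)$ to $(t_1, A_1)$ — activity is zero at
  injection and imaging starts at 1 h, so a linear rise is the natural
  interpolant; `none` and `constant` are provided because other software
  makes other choices. A single-scan curve forces `none` + physical tail:
  one sample carries no information about the uptake phase.

Fits are deterministic: mono-exponential fits are seeded by log-linear
regression and refined by Levenberg–Marquardt least squares on the linear
scale; bi-exponential fits seed the terminal component from the late
samples and the fast component from the first-sample residual, with
amplitude signs unconstrained so uptake-shaped curves (negative fast
amplitude) fit naturally. There are no random restarts, so results are
bit-reproducible. A bi-exponential fit that fails falls back to
mono-exponential and the returned model is flagged (`converged = FALSE`).
Non-decaying data flag the model and clamp the rate to physical decay
rather than erroring, leaving the decision to the caller.

Per-voxel TIA maps (`voxelTiaMap`) integrate each voxel's own samples but
extrapolate every voxel's tail with its *organ's* terminal rate, not a
per-voxel fit: five noisy samples per voxel would make per-voxel rate
estimates noise-dominated, and whole-organ tail fitting is what the
compared voxel engines do. `organwise` mode instead integrates the organ
total curve and redistributes the organ TIA proportionally to the
time-averaged voxel activity; the organ total is conserved by construction,
and for uniform kinetics the two modes agree (tested to 0.5 %).

Units are fixed throughout: times in hours, activities in MBq, TIA in
MBq·s (1 MBq·s = 10⁶ decays), kernels in Gy/(MBq·s), doses in Gy.

# The voxel engine

Convolution is frequency-domain with zero padding of at least the kernel
half-width per axis (rounded up to FFT-friendly sizes), which makes
wrap-around impossible by construction; the result is cropped back to the
grid. The test suite checks it against a direct triple-loop sum to 1e-9 on
random instances up to 24³, and checks the energy audit
$\sum_i D_i m_{vox} = \sum_j \tilde{A}_j \times 10^6 \times E_{retained}$
to 1e-6 when nothing escapes the grid.

The mask-before-convolution switch reproduces a behavioural difference
between real voxel engines: masking zeroes the TIA outside the region of
interest before convolving, which removes background and cross-region
contributions (per-voxel dose can only drop; tested as an inequality).

**Kernels.** The S-value matrices of the software this package emulates
were never published, so absolute kernel values are user territory:
kernels load from CSV (`loadKernelCsv`, with an inversion-symmetry check
and an opt-in completion from unique offsets). For self-contained use, a
parametric generator (`buildParametricKernel`) splits the ¹⁷⁷Lu energy
budget per decay — 0.147 MeV electron, 0.033 MeV photon, editable in
`inst/extdata/nuclides.yaml` — into a locally deposited fraction, a
Gaussian-spread beta remainder (r.m.s. range in mm), and an optional
photon term $\propto e^{-\mu r}/r^2$ (default μ = 0.011/mm, soft tissue
at ~200 keV) normalized against its whole-space integral $4\pi/\mu$.
Energy lost to support truncation is recorded in `energyRetained`, never
silently renormalized, so energy audits stay exact. Anisotropic voxels
(e.g. 3.9×3.9×3.5 mm) are supported by building or loading the kernel on
that spacing; there is no kernel resampling — a spacing mismatch beyond
1 % is an error.

DVHs are cumulative volume-fraction-above-dose curves on 256 uniform bins
from 0 to the region maximum by default, edges inclusive on the left.

# The organ engine

`organDose` applies reference-mass scaling $m_{ref}/m_{true}$ to the
self-dose term only: for ¹⁷⁷Lu the self term is electron-dominated and
scales inversely with target mass, while cross-organ photon terms depend
on geometry, not mass, and are left unscaled. The sphere model defaults to
full local electron deposition ($\phi = 1$, photons omitted):
$D = \tilde{A} \times 10^6 \Delta_{np} / m$ at unit density. When an
absorbed-fraction table is supplied, $\phi(m)$ is interpolated in
log(mass)–log(φ) space (absorbed fractions are near power laws in mass);
extrapolation outside the table is an error, not a guess. Proprietary
phantom S factors and fitted sphere dose factors are not shipped; the
module is table-driven.

This φ = 1 ceiling is what makes the organ route read systematically high:
with any energy-conserving spread kernel, the voxel mean over the same
region is strictly lower because energy leaks across the surface. The
package demonstrates the whole ordering on synthetic inserts: at equal
volume and concentration the deficit ranks torus > pear/tube > ellipsoid >
sphere, tracking surface-to-volume ratio.

# Renal BED

Per treatment cycle,
$BED_i = D_i\left[1 + \frac{T_{rep}}{T_{rep}+T_{eff}}\frac{D_i}{\alpha/\beta}\right]$,
the linear-quadratic model with mono-exponentially decaying dose rate:
the Lea–Catcheside factor reduces to $\lambda/(\lambda+\mu) =
T_{rep}/(T_{rep}+T_{eff})$. Defaults α/β = 2.6 Gy and T_rep = 2.8 h are
literature values for kidney, not study-specific measurements, and are
plainly editable; T_eff should come from the patient's renal TAC fit.
Cycle-specific parameters are supported because it is unstated whether
trial dosimetry used per-cycle or population half-lives — both are one
call. Cumulative limits: 46 Gy BED (28 Gy with risk factors).

# Agreement statistics

Lin's CCC uses population (1/n) moments, Lin's original estimator.
Confidence intervals use the Fisher z-transform (the published analysis
used a commercial statistics package without stating its CI method; the
z-transform is the standard default and is reported, not asserted against).
Bland–Altman limits are mean ± 1.96 SD of per-pair differences, by default
as a percentage of the reference method. The relative-difference
convention is fixed as 100·(voxel − comparator)/comparator, verified to
reproduce the printed toroid bounds (−52 %, −25 %) from the printed dose
values. Missing table entries are flagged, never zero-filled, and deleted
pairwise per comparison; pooled summaries are means over all complete
organ–patient pairs, which equal the pair-count-weighted means of
per-organ summaries.

**A documented irreproducibility.** The packaged transcription of the
published sample-A per-patient table (50 cases, organ-level vs voxel
doses in Gy/GBq) supports the printed liver concordance (computed 0.970
vs printed 0.97) but not the printed spleen (computed 0.970 vs 0.85) or
kidney (computed 0.936 vs 0.55) values; population vs sample moments,
listwise vs pairwise deletion and log-scale variants were all checked.
The printed table is also internally inconsistent with the accompanying
direction-of-difference claim (the voxel doses in it are systematically
*higher*, not lower). The likely cause is that the published concordances
were computed on unrounded per-patient values on another scale (e.g. Gy,
scaled by per-patient injected activity), which cannot be reconstructed
from the printed data. `reproduceStudyTables()` reports these rows with
`pass = FALSE` rather than hard-coding the printed values, and the
corresponding acceptance expectations are left failing by design.

# The synthetic phantom generator

The generator emulates the three physical phantoms used for standard-
condition testing: a homogeneous 5640 ml cylinder at 0.25 MBq/ml; eleven
geometric inserts (toroids, ellipsoids, pears, tubes, 2.8–31.2 ml) at
1.53 MBq/ml in cold background; and anthropomorphic organ surrogates
(lesion 8.34, pancreas 0.99, kidneys 0.81/0.82, spleen 1.10, liver
0.53 MBq/ml over a 0.03 MBq/ml background). Only insert volumes and
equivalent diameters were ever published, so shape aspect ratios are
package choices, fixed once and exposed in the recipes/parameters:
torus major:minor = 3:1, ellipsoid semi-axes 1.6:1.2:1, pear = two fused
spheres with radius ratio 1.6:1 and centre separation equal to the large
radius, tube length:diameter = 4:1, cylinder height = diameter. Each
shape's free scale is solved analytically so the exact solid has the
target volume; insert positions in the packaged recipes are arbitrary
non-overlapping placements.

**Rasterization rule.** Coordinates are voxel-centre based; a voxel is
included when at least half of its supersample points (its centre for
`supersample = 1`) lie inside the analytic surface. Binary masks quantize
the volume: smooth convex shapes land within ~1 % of target at 1 mm
voxels with 3× supersampling, while flat-faced solids (cylinder, tube)
and tight curvature (small toroids) can deviate by a few percent, and the
error shrinks with voxel size but not strictly monotonically for
flat-faced shapes (face position aliases against the voxel lattice). The
tests assert monotone convergence for the curved shapes and volume
tolerances per shape class. Downstream dose computations always use the
rasterized volume as the true volume of the digital object — that is what
is painted and convolved.

**Degradation model.** `simulateSpect` applies an isotropic Gaussian PSF
of stated FWHM (voxel-integrated, unit-sum kernel: activity is conserved
up to grid-boundary truncation) and optional Poisson resampling of counts
at a calibration factor (default 1000 counts/MBq) under a fixed seed.
This emulates resolution loss (partial-volume effect: a 17 mm sphere at
10 mm FWHM under-recovers, tested) and count noise, *not* the real
projection/reconstruction chain — no attenuation, scatter, collimator
response or reconstruction artefacts. Passing tests therefore demonstrate
correctness of the dose and statistics machinery on plausible inputs, not
quantitative fidelity of any specific scanner.

**Patient kinetics.** `simulatePatientTacs` draws organ curves
$A(t) = A_0(e^{-\lambda_w t} - e^{-\lambda_u t})$ sampled at the 5-scan
clinical schedule (1, 4, 24, 44, 72 h). Defaults are typical of
¹⁷⁷Lu-DOTATOC: kidneys $A_0$ = 150 MBq, washout half-time 50 h, uptake
1 h; liver 80 MBq/65 h/2 h; spleen 60 MBq/70 h/1.5 h, with mean-preserving
log-normal inter-patient variation (CV 40–60 % on amplitude, 20 % on
rates). The washout rate is bounded below by physical decay — no organ
can clear slower than the nuclide decays. These are population-scale
choices for generating realistic test cases, not fitted to any cohort.

# Numerical choices and degenerate inputs

* FFT convolution pads to `nextn` sizes (factors 2, 3, 5); tiny negative
  round-off in dose maps is clamped to zero.
* Fit seeding is deterministic (log-linear / curve peeling); negative
  fitted activities are clamped to zero at integration with the fit
  flagged.
* Empty regions (all-zero activity) get zero TIA and physical-decay
  tails instead of attempting a degenerate fit.
* DVH of an empty VOI, zero reference doses in percentage differences,
  missing S-factor pairs, non-increasing schedules, shapes exceeding the
  grid, asymmetric kernels and fractions outside [0, 1] are explicit
  errors (or warn-and-drop where the statistics literature does so, e.g.
  zero-reference Bland–Altman pairs).

# Problem sizes

The shipped tests and examples run on 2 mm isotropic grids (finer than
the 4.8 mm clinical reconstruction, so geometry effects are resolved) with
inserts up to ~30 ml, kernels up to 11³ voxels, and the full cylinder
study at 2 mm (~1.6 M voxels); the whole suite completes in well under a
minute on one core. Larger grids scale as the FFT.

# Known limitations

* No DICOM/DICOM-RT, no registration, no PVE correction (the activity
  images are taken as given; a PVE-corrected image can be passed in).
* Kernel resampling is not implemented; build or load kernels on the
  target spacing.
* The parametric kernel is a three-component approximation, not a Monte
  Carlo-derived S-value matrix; absolute synthetic-phantom doses are
  illustrative, and no published absolute dose is asserted against them —
  only agreement statistics computed from published tables are.
* Organ cross-dose requires a user S-factor table; none of the
  proprietary phantom tables ship with the package.
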