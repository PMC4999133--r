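---
title: "Comparing spinal-cord diffusion-MRI acquisition protocols with cordti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing spinal-cord diffusion-MRI acquisition protocols with cordti}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In vivo diffusion MRI of the mouse spinal cord must trade off three
acquisition resources under a fixed scan-time budget (roughly 35 minutes
per animal): the number of diffusion-encoding directions, the diffusion
weighting b, and the number of averages/repetitions that determine SNR.
`cordti` implements a simulation-based comparison of three archetypal
strategies:

* **Protocol A** — 126 directions, b = 700 s/mm², 10 b0 volumes,
  6 complex-domain averages, 1 repetition;
* **Protocol B** — 12 directions, b = 1200 s/mm², 5 b0, 4 averages,
  15 magnitude-domain repetitions;
* **Protocol C** — 2 directions (slice and read axes) at
  b = 200, 400, 800, 1200, 1500 s/mm², 5 b0, 4 averages, 20 repetitions.

Protocols A and B support a full diffusion-tensor fit; protocol C is
rank-deficient for the tensor (2 directions cannot span the 6 tensor
degrees of freedom) and is analysed with the two-direction estimator.

## Models

### Signal

Per voxel, the mono-exponential tensor model
\(S = S_0 \exp(-b\, g^\top D g)\) with \(D\) a symmetric positive-definite
3×3 tensor (µm²/ms; b stored internally in ms/µm², so 1.2 ≙ 1200 s/mm²).
An optional bi-exponential mode
\(S = S_0 [f e^{-b g^\top D_f g} + (1-f) e^{-b g^\top D_s g}]\)
exists *only as a simulation option*: it generates the b-dependent
apparent-diffusivity decrease that makes low-b and high-b protocols
disagree; nothing fits it.

### Estimators

The tensor is fitted by the log-linear system
\(\log S = X\beta\), where each row of \(X\) is
\([-b g_x^2, -b g_y^2, -b g_z^2, -2b g_x g_y, -2b g_x g_z, -2b g_y g_z, 1]\).
`ols` is plain least squares; the default `wls` re-weights once with the
squared predicted signals (a standard one-pass WLS; both are exact on
noiseless mono-exponential data). Signals ≤ 0 are floored at machine
epsilon times the per-voxel signal maximum before the log and flagged;
a voxel whose WLS normal equations are numerically singular falls back to
its OLS solution. Negative fitted eigenvalues are not clamped for
MD/AD/RD; FA is computed on the raw eigenvalues, then clipped to [0, 1];
both events are flagged per voxel rather than silently repaired.

Scalar metrics follow the eigenvalues \(\lambda_1 \ge \lambda_2 \ge
\lambda_3\): MD = mean, AD = \(\lambda_1\), RD = mean of the two smaller,
FA = \(\sqrt{3/2}\,\sqrt{\sum(\lambda_i - \mathrm{MD})^2}/\sqrt{\sum
\lambda_i^2}\).

For the two-direction protocol the apparent diffusivities along the slice
(\(\mathrm{ADC}_s\)) and read (\(\mathrm{ADC}_r\)) axes come from a joint
log-linear fit across that direction's b-values plus all b0 volumes
(intercept shared across b-values — the alternative of fixing S0 from the
b0 mean was rejected because the joint fit is exact on noiseless data and
uses all volumes symmetrically). Derived quantities:
\(AD_C = \mathrm{ADC}_s\), \(RD_C = \mathrm{ADC}_r\),
\(MD_C = (\mathrm{ADC}_s + 2\mathrm{ADC}_r)/3\), and \(FA_C\) by the
standard FA formula applied to the triple
\((\mathrm{ADC}_s, \mathrm{ADC}_r, \mathrm{ADC}_r)\). For an axisymmetric
tensor whose principal axis coincides with the slice axis this equals the
tensor FA and MD exactly — the degeneracy identity that the acceptance
suite checks to 1e-12.

The angular deviation is \(\theta = \arccos(|v_1 \cdot s|)\) (degrees,
[0, 90]; absolute value because fiber orientation is sign-ambiguous).
When \(\lambda_1 = \lambda_2\) within tolerance, \(v_1\) is arbitrary and
\(\theta\) is reported as missing rather than as a random angle.
Frame-projected metrics use the diagonal tensor components in the imaging
frame: \(MD'\) is exactly MD (trace invariance); \(FA'\) defaults to the
three-diagonal form — forced by that exact-MD identity — with a
`read_only` RD′ switch matching the two-direction geometry.

### Noise and averaging

Magnitude MRI noise is Rician: each reconstructed volume is
\(\sqrt{(S + n_{re})^2 + n_{im}^2}\) with
\(n_{re}, n_{im} \sim N(0, \sigma/\sqrt{N_A})\). The \(N_A\) averages are
combined in the complex domain (k-space averaging, as on the scanner);
the \(N_R\) repetitions are reconstructed independently and averaged in
the magnitude domain (registration-then-averaging). This split matters:
magnitude averaging does not remove the Rician floor, so protocol A
(all-complex averaging, one repetition) and protocols B/C (few complex
averages, many magnitude repetitions) have genuinely different noise
characters at matched total scan time.

## The phantom: what it emulates, and what it does not

The synthetic cohort emulates the study design the package targets:
axial slices of the lumbar cord (default grid 128×180×8 at
0.078 × 0.109 × 0.8 mm; tests and the acceptance suite run a down-scaled
32×32×4 grid, which changes only ROI voxel counts, never tissue
parameters or noise), six ROIs per slice — an outer white-matter annulus
split into ventral/dorsal/ventro-lateral/dorso-lateral sectors and an
inner gray-matter region split ventral/dorsal — and two groups
(WT controls and a G93A ALS model) at two ages.

Numerical choices, made once:

* **Tissue parameters** (no numeric ground truth is published for this
  experiment, only box plots): WM AD = 1.5, RD = 0.25 µm²/ms; GM
  AD = 0.85, RD = 0.65; S0(WM) = 0.8·S0(GM) = 800 — typical rodent-cord
  literature values giving WM FA ≈ 0.81, GM FA ≈ 0.16.
* **noise_sigma = 130** (S0 units): chosen so protocol A's raw WM b0 SNR
  is ≈ 15 (reported raw SNR always exceeded 10) while protocol B/C
  single-repetition diffusion-weighted SNR falls just below 10 (the one
  reported exception, before averaging), and averaged B/C SNR is several
  times A's.
* **subject_cv = 0.05**: 5% multiplicative biological variation, one draw
  per tissue per subject, applied jointly to AD and RD. A consequence to
  keep in mind: ground-truth FA then carries *no* biological variance, so
  inter-subject FA variability is purely estimation noise — consistent
  with treating age-matched controls as biologically homogeneous.
* **Disease effects**: the study reports effects only in SD units, so the
  generator injects fractional ground-truth shifts whose induced signs
  match the symptomatic-stage pattern — FA/MD/AD down everywhere, RD up
  in WM and down in GM: WM AD −15%, RD +8%; GM AD −12%, RD −10% at
  week 17, one third of that at week 10. An `FA` entry in
  `disease_effects` instead adjusts RD by root-finding at fixed AD.
* **Geometry**: the cord axis is the slice axis except in dorso-lateral
  WM, tilted 10° — so the angular-deviation analysis has structure to
  find (reported WM deviations run 7–14°, largest dorso-laterally).

Not modelled: EPI/susceptibility/eddy-current artifacts, physiological
motion (registration is upstream preprocessing), partial-volume mixing at
tissue borders, and any microstructural detail beyond the (bi-)exponential
tensor. A green test therefore establishes correctness of estimation and
statistics *given* this world, not fidelity of the world itself.

## Statistics

All standard deviations are sample (n−1) SDs — n = 7 per group is small.
SNR = ROI mean / background SD; CNR = WM−GM mean difference over the RMS
of the two SDs, signed. Inter-subject CV = SD of per-subject ROI means /
their mean; intra-subject CV = within-ROI SD/mean per subject, averaged
across subjects (per-subject values are kept for protocol-to-protocol
significance tests). Effect size = case mean − control mean, divided by
the control SD, signed. The Mann-Whitney test enumerates the exact
permutation null when n+m ≤ 16 and the pooled sample is tie-free
(enumeration is cached per sample-size pair); ties or larger samples use
the tie-corrected, continuity-corrected normal approximation. Spearman's
rho is the Pearson correlation of mid-ranks with exact enumeration up to
n = 8 and the t approximation beyond. No multiple-testing correction is
applied by default (per-ROI testing at p < 0.05, uncorrected); a
Benjamini-Hochberg switch exists. Timepoint comparisons are unpaired —
consistent with the group-SD effect-size definition; pairing was left
unspecified upstream and is not guessed.

## Design decisions worth recording

* **b-matrix**: pure \(b\,gg^\top\); imaging/crusher cross terms are
  ignored (no b-matrix is published, and the mono-exponential model
  depends on timing only through b).
* **Direction sets**: the original 126- and 12-direction tables are not
  published; any uniform antipodal set is treated as equivalent.
  `generate_directions()` minimizes antipodal electrostatic-repulsion
  energy by projected gradient descent with backtracking (tolerance 1e-8,
  up to 1000 iterations, seeded restarts); built-in protocols use fixed
  internal seeds so protocol objects are reproducible across sessions.
  For n = 3 the optimizer recovers the orthogonal triad to < 0.5°, for
  n = 6 the icosahedral layout's energy.
* **Rician-bias demonstration**: the FA-inflation-at-low-SNR mechanism is
  probed with a minimal 6-direction b = 700 scheme. With 126 directions
  the eigenvalue-repulsion bias is averaged nearly away, and at b = 1200
  with b0 SNR 5 the Rician floor *compresses* the axial attenuation and
  pushes FA down instead — an instructive interaction, but not the
  mechanism under test. Six directions is also what earlier in vivo
  mouse-cord studies actually used.
* **Null false-positive check**: with 24 cells at nominal α = 0.05 the
  chance of zero significant cells is ≈ 0.29, so a two-sided interval
  like [0.01, 0.10] on the false-positive *fraction* rejects a correct
  implementation almost a third of the time. The acceptance suite
  therefore checks the one-sided binomial bound (≤ 4/24,
  P(X > 4) ≈ 0.007).
* **Configs are JSON** (via `jsonlite`); no YAML reader is assumed.
* **NIfTI-1 I/O is implemented in-package** (uncompressed `.nii`,
  float32/float64/int16/int32, identity rotation with voxel sizes in the
  sform): no NIfTI-capable R package is available in the supported
  environment. The test suite cross-validates the codec against
  `nibabel` through the system `python`.
* **b0 classification threshold**: 50 s/mm², tolerant of vendor
  near-zero b-values.

## Known limitations

* The phantom's cross-section is an idealized ellipse/annulus; ROI
  shapes, partial voluming and per-slice anatomical variation are absent.
* Protocol C's read axis is the phantom x axis exactly; real
  read/phase-axis obliquity is not simulated.
* WLS uses a single re-weighting pass (as is conventional); no robust or
  positivity-constrained fitting.
* Intra-subject CV interprets within-ROI dispersion as noise; in real
  data it also contains anatomy.
* Effect sizes on synthetic cohorts are larger than the published
  SD-unit values whenever a metric has little inter-subject variance by
  construction (see FA above); the pipeline's sign and ordering
  properties — not ES magnitudes — are the reproduction targets.

## A worked run

```{r, eval = FALSE}
library(cordti)
cfg <- experiment_config(grid = c(32, 32, 4), n_per_group = 7,
                         timepoints = "week17", protocols = c("A", "B", "C"),
                         seed = 1, out_dir = "report")
bundle <- run_experiment(cfg)
head(bundle$best_protocol)   # argmin inter-subject CV per metric/ROI
head(bundle$comparisons)     # effect sizes and Mann-Whitney p per cell
```

Every number in the report tables is recomputed at run time; the
acceptance script (`scripts/acceptance.R`) re-derives the acceptance
quantities the same way.
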