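# cordti

Acquisition-protocol comparison for in vivo diffusion MRI of the mouse
spinal cord.

## What problem this solves, and for whom

Preclinical spinal-cord diffusion MRI has to spend a fixed scan-time
budget (about 35 minutes per anaesthetized mouse) across three competing
resources: the number of diffusion-encoding directions, the diffusion
weighting *b*, and averaging/repetitions (SNR). `cordti` is for imaging
methodologists who want to rank such protocols *before* scanning: it
simulates synthetic spinal-cord cohorts under three archetypal protocols,
estimates the standard diffusion-tensor metrics, and computes the
variability and group-discrimination statistics on which protocol
rankings are based.

The three built-in protocols:

| Protocol | Directions | b (s/mm²) | Nb0 | NA | NR | Estimator |
|---|---|---|---|---|---|---|
| A | 126 | 700 | 10 | 6 | 1 | diffusion tensor |
| B | 12 | 1200 | 5 | 4 | 15 | diffusion tensor |
| C | 2 (slice, read) | 200–1500 (5 shells) | 5 | 4 | 20 | two-direction ADC |

## The models at the core

Per voxel the signal is `S = S0 exp(-b gᵀ D g)` with `D` a symmetric 3×3
tensor (µm²/ms); an optional bi-exponential mixture is available as a
*simulation* option to create b-dependent apparent diffusivities. Noise
is Rician: magnitude of complex Gaussian noise at `sigma/sqrt(NA)`, with
the NR repetitions averaged in the magnitude domain. The tensor is fitted
by log-linear least squares (OLS, or the default one-pass WLS) and
summarized by eigenvalue metrics

```
MD = (λ1+λ2+λ3)/3,  AD = λ1,  RD = (λ2+λ3)/2,
FA = sqrt(3/2) · sqrt(Σ(λi−MD)²) / sqrt(Σλi²)
```

Protocol C uses apparent diffusivities along the slice (`ADC_s`) and read
(`ADC_r`) axes: `AD_C = ADC_s`, `RD_C = ADC_r`,
`MD_C = (ADC_s + 2 ADC_r)/3`, and `FA_C` from the standard FA formula on
`(ADC_s, ADC_r, ADC_r)` — identical to the tensor values when the cord is
aligned with the slice axis.

Statistics: SNR (ROI mean / background SD), signed CNR between WM and GM,
inter-subject CV (SD of per-subject ROI means / their mean),
intra-subject CV (within-ROI SD/mean, averaged across animals), signed
effect size `(mean_case − mean_control)/SD_control`, two-sided
Mann-Whitney (exact enumeration for n+m ≤ 16 tie-free), Spearman rank
correlation, and the angular deviation `θ = arccos(|v1·s|)` of the
principal eigenvector from the slice axis.

## A worked example

```r
library(cordti)
builtin_protocol("B")
#> <acquisition_protocol B> NA=4 NR=15
#> <gradient_scheme> 17 volumes (5 b0 + 12 weighted), b in {1.2} ms/um^2

cfg <- experiment_config(grid = c(32, 32, 4), n_per_group = 7,
                         timepoints = "week17", protocols = c("B", "C"),
                         seed = 1)
bundle <- run_experiment(cfg)
bundle
#> <report_bundle> hash=3c7cf998 seed=1
#>   840 roi_stats rows, 48 comparisons, 24 best-protocol cells

head(bundle$best_protocol, 4)
#>   metric  roi timepoint best           cv   tie
#> 1     FA  vWM    week17    B 0.0015008887 FALSE
#> 2     FA  dWM    week17    B 0.0009052385 FALSE
#> 3     FA vlWM    week17    B 0.0014649872 FALSE
#> 4     FA dlWM    week17    B 0.0019364757 FALSE

subset(bundle$comparisons, metric == "AD" & protocol == "B",
       c(metric, roi, es, p, significant))
#>    metric  roi        es            p significant
#> 13     AD  vWM -4.418777 0.0005827506        TRUE
#> 14     AD  dWM -7.015396 0.0005827506        TRUE
#> 15     AD vlWM -5.885921 0.0005827506        TRUE
#> 16     AD dlWM -3.071772 0.0005827506        TRUE
#> 17     AD  vGM -3.653387 0.0023310023        TRUE
#> 18     AD  dGM -2.137614 0.0005827506        TRUE
```

Reading it: the 7-vs-7 synthetic cohort carries a symptomatic-stage
disease effect (axial diffusivity reduced ~15% in white matter), and the
12-direction protocol recovers it as large negative effect sizes with
exact Mann-Whitney p ≈ 0.0006 (the smallest two-sided p attainable at
n = m = 7) in every ROI. The best-protocol table shows protocol B winning
the inter-subject-CV comparison for FA in white matter — the
few-directions/high-b design is the more reproducible one, which is the
qualitative protocol ranking the simulation reproduces. Effect-size
*magnitudes* exceed in vivo values because the phantom's controls are
nearly homogeneous by construction; signs and orderings, not magnitudes,
are the reproduction targets (see the vignette).

Every run is deterministic given `seed`; tables are written as TSV (with
a provenance header) when `out_dir` is set. A command-line interface
wraps the same pipeline:

```sh
Rscript inst/cli/cordti.R run --config cfg.json --seed 1 --out report/
```

## Layout

- `R/schemes.R` — protocols, direction generation, design matrices, FSL I/O
- `R/phantom.R` — synthetic cord cohorts, Rician noise, disease effects
- `R/dwi_io.R` — NIfTI-1 codec, study bundles, ROI extraction
- `R/estimators.R` — tensor/two-direction fits, metrics, angular deviation
- `R/stats.R` — SNR, CNR, CV, effect size, Mann-Whitney, Spearman
- `R/pipeline.R`, `R/cli.R` — experiment orchestration and CLI
- `vignettes/protocol-comparison.Rmd` — models, assumptions, design choices
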