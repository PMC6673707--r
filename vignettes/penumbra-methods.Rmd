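---
title: "Methods: lesion penumbra mapping in white matter tracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion penumbra mapping in white matter tracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penumbra)
```

## The model and its assumptions

White matter hyperintensities (WMH) sit inside a halo of subtly damaged
normal-appearing white matter (NAWM): fractional anisotropy (FA) is
depressed and mean diffusivity (MD) elevated near the lesion, relaxing
toward normal values with distance. This package measures that halo
*within tracts*: each tract (a tractography posterior-probability map,
binarized at probability > 1%) is split into its WMH intersection
(tract-WMH) and its NAWM portion (tract-NAWM), and the diffusion metrics
are averaged over equidistant contours at 2, 4, 6, 8, 10 mm from the
lesion edge, restricted to tract-NAWM.

Because the approach to normal values is asymptotic rather than linear,
the trajectories are modelled against `log(distance + 1)` (the lesion
itself is coded as distance 0, so the intercept is the within-lesion
level):

$$y_{ptd} = \beta_0 + \beta_1 \log(d + 1)
  + b_{0p} + b_{1p}\log(d+1) + c_{0t} + c_{1t}\log(d+1)
  + \varepsilon_{ptd}$$

with crossed (not nested) random intercepts and log-distance slopes for
participant $p$ and tract $t$, fitted by REML. A second family compares
intersecting against nearby lesions over the common 2–10 mm range
(`log(distance)` plus a lesion-type factor with tract-WMH as reference);
the `log(distance):type` interaction enters only when it lowers the BIC
of a maximum-likelihood refit, with ties resolved to the simpler model.
Key modelling assumptions: shell means are conditionally Gaussian and
homoscedastic (in truth their sampling variance scales with 1/voxel
count; the mixed model tolerates this but does not model it), and random
effects are independent between intercept and slope (a
variance-components formulation; penumbra analyses of this kind do not
report random-effect correlations, so none are estimated).

## Geometry: why Chebyshev distance

"Dilate by 2 mm (one voxel) per step" becomes exact geometry once a
structuring element is fixed. The default is the 26-connected 3×3×3
cube, under which one dilation step adds exactly one voxel of Chebyshev
(L∞) distance, so shell $k$ — the $k$-step dilation minus the
$(k-1)$-step dilation — is precisely the set of voxels at Chebyshev
distance $k$ from the seed. The test suite enforces this equivalence
against a brute-force distance transform (set equality over hundreds of
random masks). 6- and 18-connectivity are available
(`dilation_connectivity`), but break the clean distance interpretation
and are not the default. Diagonal neighbours are then 2·√3 ≈ 3.5 mm away
rather than 2 mm; the distances are therefore nominal ("about 2 mm per
step"), as with any voxel-based contour.

Nearby lesions are handled per 26-connected component: eligibility (a
lesion that misses the tract but whose 2–10 mm contours reach its NAWM)
is a property of a lesion, not of voxels, and one physical lesion may be
"nearby" for one tract and "intersecting" for another. Shells of
different nearby components are measured separately, then pooled per
tract × distance by voxel-count-weighted mean (the per-component table
stays available as an attribute). Any voxel already claimed by a
tract-WMH contour is excluded from nearby contours, so nearby
measurements are never contaminated by regions connected to an
intersecting lesion. Anisotropic grids are refused by default: "one step
= 2 mm" has no single meaning there. With `allow_anisotropic = TRUE` a
step is still one voxel and reported distances use the nominal step,
with a warning.

The tract partition ignores tract voxels that are neither WMH nor NAWM
(CSF-adjacent or unsegmented tissue); they count toward neither
compartment nor the `%WMHvol` denominator.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tract_threshold` | 0.01 | posterior-probability cut; strictly greater-than (a voxel at exactly 1% is background — the convention is declared and tested rather than left ambiguous) |
| `shell_step_mm` | 2 | nominal distance per dilation step; must match the (isotropic) voxel size |
| `n_shells` | 5 | shells at 2–10 mm; also the reach of nearby-lesion eligibility |
| `dilation_connectivity` | 26 | structuring element (see above) |
| `component_connectivity` | 26 | WMH component labelling |
| `md_threshold` | 1e-3 mm²/s | CSF contamination cut, strict `>`; the boundary value is retained. The whole contour (record) is excluded for both FA and MD analyses — contamination is a property of the contour, not of one metric (an `exclusion_scope = "md_only"` sensitivity option keeps flagged contours for FA). A flagged record stays in the table for accounting |
| `df_method` | satterthwaite | denominator df for Type III Wald F; `residual` available; Kenward-Roger is *not implemented* and requesting it is an error, never a silent substitution |
| `md_scale` | 1e4 | MD is rescaled before fitting so variance components are well-conditioned; estimates are reported on this scale and the factor is recorded in every result |

## The synthetic cohort: what it emulates, what it does not

`phantom_config()` / `simulate_cohort()` generate per-participant
bundles (tract probability maps, WMH mask, NAWM mask, FA, MD) with a
known planted structure:

- **Tracts**: straight tubes with a Gaussian probability profile
  (maximal on the centerline, < 1% beyond twice the nominal radius).
  Identical across participants — tract geometry variation is not the
  quantity under test.
- **Lesions**: axis-aligned ellipsoids (semi-axes 2–5 mm). Intersecting
  lesions lie fully inside their tract; nearby lesions sit at a
  Chebyshev gap of 1–3 voxels. A minimum Chebyshev separation
  (default 12 voxels) keeps every NAWM voxel within shell range
  unambiguously closest to one lesion.
- **Maps**: the planted mean is
  $\beta_0 + \beta_1\log(d_{mm}+1)$ with $d$ the *Chebyshev* voxel
  distance to the nearest WMH voxel (×2 mm), capped at 10 mm (the curve
  is frozen at its 10 mm value beyond the modelled range — behaviour
  past 10 mm is irrelevant to the analysis but must be defined).
  Voxels closest to a nearby lesion additionally receive the type
  offset. Participant and tract random intercepts/slopes are drawn once
  per participant and once per tract (crossed), Gaussian voxel noise is
  added, FA is clipped to [0,1], and a fraction of the brain-border rim
  receives CSF-like MD above 10⁻³ mm²/s.

Planted effect defaults are the magnitudes the validation suite targets:
FA slope 0.024 per unit log(mm+1) from 0.30 at the lesion; MD slope
−0.085 (×10⁻⁴ mm²/s) from 9.0×10⁻⁴; nearby offsets +0.015 (FA) and
−0.012×10⁻⁴ mm²/s (MD). Within-lesion FA/MD distributions beyond their
mean level are not specified by any source and are free phantom
parameters, not reference values.

Two generator choices deserve emphasis because they define what a green
test establishes:

1. **Chebyshev planting.** Planting the gradient in the same metric as
   the shell geometry makes zero-noise recovery *exact* (to 1e-10),
   cleanly separating statistical error from geometric error. Real
   penumbras are not Chebyshev-shaped; the phantom validates the
   machinery, not the biology.
2. **Contained intersecting lesions.** Shells grow from tract-WMH
   (lesion ∩ tract) while the planted field radiates from the whole
   lesion; if a lesion pokes out of its tract the two distances diverge
   and shell means blur across planted distances. Containment keeps the
   recovery test sharp. Real lesions straddle tract boundaries — that
   blurring is an inherent property of the tract-WMH contour method, and the
   phantom deliberately removes it rather than asking the estimator to
   absorb it.

Not emulated: curved/crossing tract anatomy, partial-volume effects,
bias fields, registration error, non-Gaussian noise, realistic lesion
shapes, within-lesion heterogeneity. A green phantom suite therefore
establishes correctness of the geometry, sampling and inference code —
not robustness to acquisition artefacts.

Per-participant random-effect and noise defaults (FA: intercept/slope
SDs 0.02/0.005 per participant, 0.02/0.005 per tract, voxel SD 0.05;
MD ×10⁻⁴: 0.3/0.05, 0.3/0.02, voxel SD 0.5) give shell means (tens to
hundreds of voxels each) realistic cohort-level scatter: between-
participant SD of a shell mean ≈ 2–3% of the FA level, slope
heterogeneity ≈ 20% of the planted slope. They were chosen once, from
typical between-subject variability of FA/MD summary measures in aging
cohorts, and are deliberately not tuned.

## Numerical choices

- **Exact binary morphology.** The 26-connected dilation is a separable
  3×3×3 maximum filter (three 1-D passes), confined to the seed's
  padded bounding box; results are identical to the naive 26-shift
  definition (tested). Component labelling is iterated minimum-label
  propagation with deterministic centroid ordering.
- **Degenerate fits.** With one participant (or a constant outcome) the
  mixed model is unidentifiable; the fit degenerates to a fixed-effects
  `lm`, flagged `degenerate`, which reproduces a noiseless planted
  slope exactly. A perfectly constant outcome reports F = 0 for its
  zero coefficients rather than 0/0 round-off noise.
- **Satterthwaite df** are computed by the variance-parameter delta
  method: the asymptotic covariance of (θ, σ) from a central-difference
  Hessian of the non-profiled REML deviance, and a central-difference
  gradient of each contrast variance. At boundary fits (a variance
  component estimated at zero) the Hessian can be singular; a
  Moore-Penrose inverse is used and, if the resulting df are unusable,
  the fit falls back to residual df with `df_method =
  "residual_fallback"` stamped into the output — never silently.
  Kenward-Roger would require the full adjusted covariance machinery;
  since the estimates and F statistics it shares with Satterthwaite are
  the quantities under test here, it is an explicit unsupported option.
- **REML vs ML.** Reported fits use REML; BIC comparisons of fixed
  effects (the interaction gate) use ML refits of both candidates, per
  standard practice. BIC ties choose the simpler model,
  deterministically.
- **MD scaling.** Raw MD (~10⁻³ mm²/s) produces variance components
  ~10⁻⁸, ill-conditioned for the optimizer; MD is fitted ×10⁴ and the
  factor recorded. On this scale the planted slope is −0.085.
- **Reproducibility.** Every stochastic stage derives its seed from the
  global seed via a fixed integer hash; a cohort is a pure function of
  its configuration, and identical pipeline configs produce
  byte-identical tables and manifests.

## Known limitations

- Only 18-ish tracts and 2-level phantom tract factors make the tract
  variance components weakly identified; Satterthwaite df can be ~1 and
  the corresponding intervals very wide. That is honest uncertainty,
  but singular fits (tract variance at zero) will under-cover.
- Euclidean or geodesic (along-tract) distance shells are out of scope;
  Chebyshev contours overestimate diagonal distances by up to √3.
- The CSF filter is a mean-MD threshold on whole contours; partial
  contamination below the threshold passes through.
- Real-data mode assumes co-registered, resampled volumes on one grid;
  no registration or resampling is performed or checked beyond the
  common-grid contract.
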