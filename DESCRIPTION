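Package: penumbra
Title: Spatial Gradients of White Matter Diffusion Metrics Around
    Hyperintense Lesions
Version: 0.1.0
Authors@R:
    person("Penumbra", "Maintainers", email = "maintainers@penumbra.invalid",
           role = c("aut", "cre"))
Description: Quantifies the "penumbra" of microstructural damage in
    normal-appearing white matter (NAWM) surrounding white matter
    hyperintensities (WMH). Partitions tractography-derived white matter
    tracts against WMH and NAWM masks, builds 2 mm-increment morphological
    distance shells around tract-intersecting and nearby non-intersecting
    lesions, samples mean fractional anisotropy (FA) and mean diffusivity
    (MD) per shell, and fits repeated-measures linear mixed models of the
    diffusion metrics against log-distance with crossed random effects for
    participant and tract. Includes a synthetic phantom cohort generator
    with planted log-distance gradients for end-to-end validation, a
    minimal NIfTI-1 reader/writer, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
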