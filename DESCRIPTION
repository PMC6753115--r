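Package: patchgrade
Title: Patch-Based Probability Grading and Normative Morphometry on
    Synthetic Brain Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, desk-scale pipeline for patch-based
    probability grading of the hippocampus and entorhinal cortex.
    Provides a synthetic 3D phantom generator emulating a five-group
    clinical continuum (cognitively healthy through Alzheimer's
    dementia), T1-style preprocessing stand-ins (nonlocal-means
    denoising, log-domain polynomial bias-field correction, rigid
    registration to template space, linear intensity normalization,
    patch-based brain extraction), a nonlocal patch-match engine that
    simultaneously fuses structure labels and grades each voxel's
    similarity to healthy versus disease template libraries,
    covariate-adjusted normative Z-scores with segmentation quality
    control, education-stratified clinical group classification, and
    the group-comparison statistical battery (one-way ANOVA, Tukey HSD,
    Benjamini-Hochberg FDR, Cohen's d, chi-square, moderation models).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
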