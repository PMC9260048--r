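Package: efnet
Title: Network Engagement of TMS Targets from E-Field-Defined Cortical Seeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying which resting-state functional networks are
    engaged by transcranial magnetic stimulation (TMS) targets. Cortical seed
    regions are defined by thresholding simulated electric-field (E-field)
    magnitude maps on a triangulated surface mesh; seed-averaged functional
    connectivity (FC) is computed against dense vertex-by-vertex connectomes;
    each suprathreshold vertex is assigned to the canonical network it is most
    strongly connected to, yielding per-subject network-engagement profiles.
    A three-variant framework (subject E-field x group FC, template E-field x
    subject FC, subject E-field x subject FC) separates cortical-geometry-driven
    from connectivity-driven inter-subject variability, with repeated-measures
    ANOVA, Tukey-corrected post hocs and cross-variant correlations. Includes a
    fully synthetic cohort generator (icosphere meshes, Gaussian focal E-field
    surrogates, latent-factor connectomes with planted network structure) so the
    whole pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
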