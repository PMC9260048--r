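---
title: "Quantifying network engagement of TMS targets: model, surrogates and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying network engagement of TMS targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Transcranial magnetic stimulation (TMS) of frontal targets — classically the
left dorsolateral prefrontal cortex (dlPFC, localized via the 10–20 scalp
position F3) and more recently the orbitofrontal cortex (OFC, via Fp1) —
produces highly variable physiological and therapeutic outcomes. Two sources
of inter-subject variability are commonly invoked: *cortical geometry*
(individual skull and cortical folding reshape the induced electric field,
so the same coil position stimulates different tissue in different people)
and *functional connectivity* (the same stimulated patch is coupled to
different downstream networks in different people).

`efnet` implements, as a tested and reusable pipeline, an analysis that
separates these two sources:

1. **Seed definition.** The induced E-field magnitude map on the cortical
   surface is thresholded at 0.9 V/m; the suprathreshold vertex set is the
   stimulated *seed*. Seed size is reported in mm², computed directly from
   the mesh triangles.
2. **Seed connectivity.** Against a dense (vertex × vertex) Pearson
   connectome, the seed's FC map is the plain average correlation of the
   seed's rows to every vertex.
3. **Network engagement.** Each seed vertex is assigned, winner-take-all,
   to the canonical network (of eight: Vis, SomMot, DAN, VAN, Limbic, FPN,
   TempPar, DMN) to which its mean signed correlation is highest. The
   percentage of seed vertices per network is the *engagement profile* —
   the spider-plot statistic.
4. **Variant framework.** The pipeline is run three ways per target:
   subject E-field × group FC (`GEOM`: geometry variability only),
   template E-field × subject FC (`FCONLY`: connectivity variability only),
   and subject E-field × subject FC (`COMBINED`: both). Comparing
   engagement across variants — via repeated-measures ANOVA over the
   network factor, Tukey-corrected post hocs, paired target contrasts, and
   cross-variant Pearson correlations of per-network engagement — shows how
   much each source contributes, and how far normative (template/group)
   data can substitute for individual data.

Because the real analysis rests on proprietary-scale neuroimaging inputs
(32k-vertex cortical meshes, 91k-row dense connectomes, biophysical FEM
E-field simulations), the package ships a *synthetic cohort generator* that
reproduces the structure of those inputs at desk scale, so every step of the
pipeline can be exercised, validated against closed forms and brute-force
oracles, and re-run deterministically.

## The synthetic cohort

### Surface and parcellation

The cortical hemisphere is emulated by an icosphere: subdivision level 4
gives 2562 vertices and 5120 faces (counts scale as `10·4^L + 2` and
`20·4^L`), default radius 12 mm. The radius was chosen once so that a seed
of a few tens of mm² spans a few dozen vertices — about the same
vertices-per-seed resolution the real 32k meshes give to the reported
12–112 mm² seeds. The parcellation divides the sphere into `n_parcels`
(default 8) contiguous Voronoi cells around farthest-point-sampled centers,
each parcel mapped to one of the eight canonical networks. The two parcels
containing the stimulation foci are *anchored*: their centers are the foci
themselves and their networks are fixed (VAN under the dlPFC-like focus,
DMN under the OFC-like focus), mirroring the empirical finding that these
networks dominate those targets.

### E-field surrogate

Biophysical field simulation is out of scope; what the downstream analysis
needs is a focal, subject-varying suprathreshold patch. The surrogate is a
Gaussian of Euclidean distance from a focus vertex:

    value(v) = A · exp(−‖v − c‖² / (2σ²))

with peak `A = nominal_amplitude · amplitude_factor` and width
`σ = nominal_sigma · sigma_factor`. Closed forms follow: the peak value at
the focus vertex is exactly `A`, and the 0.9 V/m isocontour lies at radius
`σ·√(2·ln(A/0.9))`. Per-subject factors are log-normal (sdlog 0.08 for
amplitude, 0.14 for width) and the focus is jittered by an isotropic 1.5 mm
Gaussian — together these reproduce the right order of relative dispersion
in thresholded seed areas. Placement defaults (dlPFC-like: A = 1.5 V/m,
σ = 4.65 mm; OFC-like: A = 1.3 V/m, σ = 3.28 mm) were calibrated once so
that 0.9 V/m seed areas land near the reported study means (~54 mm² dlPFC,
~16 mm² OFC), with the OFC field smaller and weaker, as the greater
coil–cortex distance at Fp1 dictates. Note that the package measures seed
area conservatively — only faces whose *three* vertices are suprathreshold
count — which undercounts the continuous isocontour disc `πR²` by roughly a
one-edge-length boundary band; the calibrated σ values account for this.

Subject geometry variability is represented entirely through these
subject-specific field realizations on a *shared* template mesh, not
per-subject meshes: geometry influences the analysis only via the E-field
map, so this preserves the analyzed contrast at a fraction of the cost.

### Connectome surrogate

Subject connectomes come from a latent-factor model: each network has one
iid-normal latent time series `f_n(t)`, all vertices share a global signal
`g(t)`, and vertex `i` in network `n` follows

    x_i(t) = (w·m_net(i) + δ_i)·f_net(i)(t) + w_s·g(t) + ε_i(t)

with defaults `w = 0.6`, `w_s = 0.3`, `ε ~ N(0, 0.8²)`, per-network loading
multipliers `m` (all 1 unless a dominant network is planted), and
per-subject, per-vertex perturbations `δ_i ~ N(0, 0.1²)` that act as the
subject's FC fingerprint. The Pearson matrix of one run is symmetric, has
unit diagonal, and is positive semidefinite by construction. Four runs per
subject (200 time points each) are averaged by Fisher-z transform —
mirroring the four-resting-state-run averaging of the emulated study — and
the cohort's group connectome is the Fisher-z average across subjects. A
flag (`average_order = "timeseries"`) instead averages the run time series
pointwise before correlating, since the emulated study's description is
ambiguous between the two orders; run-wise FC averaging is the default.

The exact large-T correlation implied by the model (δ = 0) is available in
closed form via `population_connectome()`: within-network
`r = (w² + w_s²)/(w² + w_s² + σ_ε²)` ≈ 0.41 at the defaults, cross-network
`r = w_s²/(w² + w_s² + σ_ε²)` ≈ 0.08 — values in the realistic range for
resting-state data. With a planted dominant network (multiplier 3), its
within-network correlation rises to ≈ 0.82. Feeding this population matrix
through the same assignment pipeline gives the analytic expectation of
engagement, the yardstick for parameter-recovery validation.

### Randomness and reproducibility

Everything derives from one `master_seed`. Each (subject, product) pair —
parameter draws, FC draws, the parcellation's center choice — gets its own
stream via a deterministic 31-bit hash, so no two subjects share
randomness, any component can be regenerated in isolation, and the whole
bundle is bitwise reproducible. The degenerate "zero FC variability"
cohort needed for variant-identity checks is an explicit flag
(`shared_fc_stream = TRUE`) that points every subject at one FC stream:
with independent streams, subject correlation matrices would differ even
with all noise scales at zero, because finite-length latent series have
realization-dependent sample correlations.

## Pipeline conventions and numerical choices

* **Inclusive threshold.** A vertex exactly at 0.9 V/m belongs to the seed,
  so the printed threshold value is inside the region it defines.
* **Conservative area rule.** A face contributes area only when all three
  vertices are suprathreshold; degenerate (collinear) faces contribute zero
  area with a warning rather than an error, since real surface extracts
  contain slivers.
* **Indexing.** Vertices are 1-based in memory (R convention) and 0-based
  in every file format (GIFTI, TSV); readers and writers convert
  explicitly.
* **Plain-mean seed FC.** Seed-averaged FC uses the arithmetic mean of r
  with no transform; Fisher z is reserved for run/group averaging of whole
  connectomes, where it is standard. Fisher-z averaging clips |r| at
  1 − 1e-7 before `atanh` and forces the diagonal back to 1.
* **Seed vertices stay in the map.** The seed FC map covers every vertex,
  including seed members (whose values include the r = 1 self term); a
  `mask_seed` flag blanks them for display.
* **Self-exclusion in assignment.** A vertex's mean FC to its *own* network
  excludes the vertex itself — otherwise the self-correlation of 1 would
  bias assignment toward the home network. Signed (not absolute) r is used
  throughout; ties go to the earlier network in the fixed order Vis,
  SomMot, DAN, VAN, Limbic, FPN, TempPar, DMN.
* **Empty seeds.** A subject whose field never reaches threshold is
  excluded from that variant with a warning and a recorded count; subjects
  are dropped pairwise from cross-variant correlations.
* **ANOVA.** The repeated-measures decomposition is the classical one
  (`SS_total = SS_subjects + SS_levels + SS_error`,
  `F = MS_levels/MS_error` on `(k−1, (k−1)(n−1))` df), cross-checked in the
  test suite against `aov`'s within-subject error stratum. Effect size is
  *partial* eta squared, `SS_levels/(SS_levels + SS_error)`. No sphericity
  correction is applied by default (a Greenhouse–Geisser option exists
  behind a flag). Tukey post hocs use the studentized-range distribution
  with the pooled `MS_error`; at two levels the adjusted p equals the raw
  p exactly (the identity is coded directly, bypassing `ptukey`'s ~1e-6
  numerical error). Zero error variance yields F = +Inf with p = 0 (or
  F = 0, p = 1 when the effect is also zero) and a warning rather than NaN.
  A paired contrast of identical vectors returns T = 0, p = 1; a constant
  nonzero difference (zero variance) is an error.
* **Spider areas.** The spider polygon with radii `r_i = percent/100` on
  the regular eight-direction fan has normalized area
  `Σ r_i·r_{i+1}/8` (cyclic); the normalization by the unit octagon is a
  package convention, as no standard one exists.
* **Display rounding.** Percentages print with one decimal and coverage
  sums as integers; files always keep full precision.

## Study conditions and problem sizes

The packaged defaults *are* the synthetic study: 40 subjects, level-4
icosphere, 8 parcels, 4 runs × 200 time points, moderate geometry and FC
variability as above. At these sizes cohort generation takes on the order
of two minutes and the variant analyses seconds. The validation suite uses
these defaults for the parameter-recovery check (a planted VAN multiplier
of 3 under the dlPFC-like seed must be recovered as the most-engaged
network in ≥ 95% of subjects, with the cohort-mean engagement within 5
percentage points of the factor-model expectation) and smaller level-2/3
meshes with 6–8 subjects for identity and property checks.

## What the synthetic validation does and does not show

The generator reproduces the *structural* features the pipeline depends on:
focal subject-varying suprathreshold patches with realistic area
dispersion, dense symmetric unit-diagonal connectomes with planted
block-correlation structure, multi-run averaging, and a group reference.
Passing tests therefore demonstrate that the pipeline's arithmetic,
conventions and statistics do what they claim, and that planted effects are
recovered at realistic noise.

They do not show anything about real cortical data: the sphere has no
gyrification, so there is no true geodesic-vs-Euclidean distinction and no
E-field depth structure; parcels are compact Voronoi cells whereas real
networks are interdigitated across the cortex, which makes synthetic
engagement profiles more concentrated than empirical ones (a seed centered
on an anchored parcel is often engaged > 90% by one network, versus the
~20–45% mixtures seen in real spider plots); and the latent-factor
connectome has no spatial autocorrelation beyond network membership, no
hemodynamics and no scanner noise structure. Headline empirical numbers
(specific percentages, F values, correlations) are therefore *not*
reproduction targets — only the printed worked arithmetic (e.g. coverage
sums of published per-network means) is checked against published values.

## Known limitations

* Single hemisphere only; no subcortical structures, so "dense" connectomes
  are cortical-vertex matrices.
* The template E-field uses identity subject parameters, so its seed area
  sits near the subject mean; in the emulated study the general-template
  head produced a notably smaller field than the subject average. Nothing
  downstream depends on this difference.
* Fisher-z averages of rank-deficient correlation matrices (time points ≪
  vertices) need not be positive semidefinite; only raw run connectomes
  carry the PSD guarantee.
* Automated naming of anatomical FC-map nodes is out of scope; the package
  exports the maps (GIFTI/TSV) for inspection.
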