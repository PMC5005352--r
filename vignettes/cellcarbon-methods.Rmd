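---
title: "Methods: from cell dimensions and amino acids to sub-seafloor biomass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from cell dimensions and amino acids to sub-seafloor biomass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellcarbon)
```

`cellcarbon` converts two kinds of laboratory tables — per-cell microscopy
dimensions and per-sample amino-acid measurements — into the quantities a
deep-biosphere study reports: corrected biovolumes, cell-specific carbon
content, carbon density, and their depth profiles. This vignette documents
the models, the tunable parameters, and the numerical and design choices
behind the implementation.

## Morphotypes and shape models

Cells are classified by the orientation-agnostic aspect ratio
$AR = \max(L,W)/\min(L,W)$: **coccoid** when $AR \le 1.3$, **filamentous**
when $AR \ge 10$, and **elongated** otherwise. Rods and prolate spheroids
are pooled as elongated, which keeps FM and SEM data comparable. Two
boundary conventions deserve comment:

* The coccoid/elongated boundary is not a community standard; cocci are
  simply "AR near 1". The default 1.3 is exposed as `coccoid_max_ar` in
  `classify_morphotype()` and `run_pipeline()` so its sensitivity can be
  tested directly.
* The band $3 < AR < 10$ falls between the "slightly elongated" and
  "filamentous" descriptions in common use; such cells are treated as
  elongated (capsule model). Continuity is the least surprising behavior,
  and the filament threshold is likewise configurable.

Volumes come from four shape models, all homogeneous of degree 3 so that
classification is scale-free and volume corrections can act multiplicatively:
sphere $(\pi/6)d^3$ on the width; capsule (cylinder with hemispherical
caps) $(\pi/4)W^2(L - W/3)$; prolate spheroid $(\pi/6)LW^2$; ellipsoid
$(\pi/6)LWH$ when an independent height exists (AFM). The capsule was
chosen over a flat-ended cylinder for rods and filaments because rounded
poles match electron micrographs of sediment rods; the prolate spheroid is
available as an explicit alternative (`cell_volume(shape =
"prolate_spheroid")`). For FM and SEM the height is assumed equal to the
width, which is implicit in using width-based solids of revolution. The
degenerate identities (capsule = prolate spheroid = sphere at $L = W$;
ellipsoid = prolate spheroid at $H = W$) are exact mathematically and are
asserted at $10^{-15}$ relative tolerance, the last floating-point ulp.

Measured tables may record the two axes in either order; the larger axis is
stored as length (with a counted warning) rather than rejecting the row,
since manual measurement order is arbitrary.

## The correction cascade

Four treatment artifacts bias observed volumes, each undone by a
multiplicative factor on the **volume** (never on linear dimensions):

| treatment | factor | applies to | origin |
|---|---|---|---|
| fixation | 1.29 | all morphotypes, FM+SEM+AFM | 22.5% volume shrinkage, $1/(1-s)$ |
| filtration | 1 (coccoid), 1.13 (others) | FM+SEM+AFM | paired filtered/unfiltered culture volumes 0.76/0.68 |
| fluorescence halo | 0.475 | FM only | stain halo inflates FM volumes ~2.1× |
| dehydration + CPD | 2.38 | SEM only | 58% shrinkage, $1/(1-0.58)$ |

The canonical factors are stored verbatim. Two of them disagree with naive
re-derivation at two decimals (0.76/0.68 = 1.1176 prints as 1.13; 1/2.1 =
0.476 is stored as 0.475): the table is what gets applied, while
`factor_from_shrinkage()` and `factor_from_inflation()` expose the
derivations so the rounding gap stays visible instead of being silently
reconciled. The halo factor is shared by all morphotypes because coccoid
reference cultures aggregate under FM, leaving the rod-derived value as the
only measurement. AFM is assigned fixation and filtration only: it images
hydrated cells and needs neither the halo nor the drying correction.
Factors and applicability are overridable through a YAML config
(`read_correction_config()`); defaults ship in the package.

Because the composite factor is a pure product, corrections are
order-independent, and simulating an observation by dividing a true volume
by the composite factor round-trips to machine precision — this is both a
test invariant and the mechanism of the synthetic generator.

## From amino acids to carbon

Total hydrolyzable amino acids (THAA, fmol cell⁻¹) convert to amino-acid
carbon by the composition-weighted mean carbon atoms per residue,
$\bar n_C = \sum_i f_i\, n_{C,i}$, over the 18 analytes of the HPLC window
using free-residue stoichiometry (acid hydrolysis restores the water of
condensation). $\bar n_C$ is bounded by 2 (pure glycine) and 9 (pure
tyrosine/phenylalanine). Analytes below detection (β-alanine, taurine,
γ-aminobutyric acid, ornithine) carry zero weight but remain registered.
Compositions are renormalized to exactly 1 before weighting; the packaged
reference rows sum to 99.5–100.2 mole %, and sums outside 95–105% trigger
a warning as a transcription guard.

Total cell carbon is
$C_{cell} = \mathrm{THAA\mbox{-}C} \times 12.011 / f_{AA}$ (fmol C ×
g mol⁻¹ = fg C), with the amino-acid-carbon share $f_{AA} = 0.55$ by
default, a culture-based macromolecular budget; 0.40 and 0.75 are the
standard sensitivity settings and any value in (0, 1] is accepted. The
estimate is exactly inversely proportional to $f_{AA}$. Results are kept
unrounded; rounding to integer fg is presentation only.

Two arithmetic caveats are inherent to the published reference inputs and
are asserted at matching tolerances in the tests: the composition-derived
THAA-C agrees with the measured THAA-C only within ~10% (inputs are printed
to 2 significant figures; e.g. 0.18 fmol × 4.64 = 0.83 vs 0.88 measured),
and one sample's total carbon recomputes to 28.4 fg where 29 was printed,
so per-sample totals are compared within ±1 fg. The mean over the seven
reference samples recomputes to 22.4 fg C cell⁻¹ from the printed inputs.

The cell-specific carbon density divides cell carbon by the
morphotype-weighted mean FM volume,
$C_d = C_{cell} / (\bar V_{cocc} f_{cocc} + \bar V_{rod} f_{rod} +
\bar V_{fil} f_{fil})$, and satisfies the exact inverse identity
$C_d \times \bar V = C_{cell}$. Multiplying cell carbon by cell abundance
(cells cm⁻³) gives sediment-integrated carbon in µg C cm⁻³ (factor
$10^{-9}$ from fg).

## Profile statistics

* **Percentiles** use linear interpolation between order statistics
  (R's type 7); a convention had to be fixed for testability and this is
  R's default and the one most plotting pipelines assume.
* **Depth trends** use fixed-effects one-way ANOVA grouped by sample.
  Volumes are log10-transformed by default because within-sample
  biovolumes are lognormal-like; the raw-scale test remains available
  (`log_transform = FALSE`). Both numerator and denominator degrees of
  freedom are reported explicitly, so either single-df reporting
  convention can be reconstructed.
* **Uncertainty** uses the percentile bootstrap (default 1000 replicates,
  95%), seeded explicitly; the caller's RNG state is restored.
* **FM/SEM concordance** is summarized by the mean log10 ratio of paired
  corrected volumes and the least-squares slope through the origin, with a
  default concordance band of ±0.05 on the log ratio (~12% on the
  geometric mean).

## The synthetic generator

Raw per-cell microscopy tables for sub-seafloor studies are rarely public,
so the generator produces studies with the statistical structure the
analysis assumes; its defaults are the study conditions, not tuning knobs:

* depth grid 0.4–60 mbsf (the seven reference depths plus a 60 m floor),
  300 cells per depth and modality;
* coccoid/elongated volumes lognormal with geometric SD 2 (≈ one order of
  magnitude within-sample spread) and median declining log-linearly from
  0.05 µm³ at the shallowest depth to 0.005 µm³ at the deepest;
* filaments 5% of the mixture, larger (0.3 → 0.08 µm³) with a tighter
  spread (GSD 1.33, ≈ half an order of magnitude);
* aspect ratios uniform per morphotype (coccoid 1–1.3, elongated 1.3–3,
  filament 10–15, the upper filament bound being an unconstrained choice);
* abundance log-linear from 10¹⁰ cells cm⁻³ at 0 mbsf to 10⁸ at 60 mbsf;
* THAA profiles drawn lognormally around the packaged reference anchors
  (GSD 1.15, a plausible analytical+biological variability; 1 reproduces
  the anchors exactly) and compositions perturbed multiplicatively
  (GSD 1.05) then renormalized to 100%.

Dimensions are back-solved from the drawn volume and aspect ratio under the
morphotype's own shape model (for coccoids the sphere uses the width, so a
cosmetic elongation up to AR 1.3 does not perturb the volume), which
guarantees shape-model consistency: observation bias (true volume divided
by the composite factor, dimensions scaled by its cube root) followed by
the forward pipeline recovers true volumes to machine precision, and FM-
and SEM-derived corrected volumes of the same cells agree exactly. All
randomness flows from one root seed with fixed per-table offsets, so a
fixed seed reproduces every table bit for bit and individual tables can be
regenerated stably.

What the generator does **not** emulate: measurement noise beyond the
deterministic treatment biases, misclassification (generated aspect ratios
never straddle the thresholds), depth-varying morphotype mixtures,
within-core spatial heterogeneity, aspect-ratio–volume dependence, or AFM
observation. Passing recovery tests therefore demonstrates that the
pipeline's algebra and plumbing are correct under the assumed statistical
structure — not that the correction factors are appropriate for any real
sediment, which only paired-method field data can show.

## Recovery testing and problem sizes

Parameter recovery is assessed over 20 seeds of the default study: at each
anchor depth, the 95% percentile-bootstrap CI of the mean log10 corrected
coccoid+elongated volume should cover the configured anchor. The recovery
rate is counted over the 40 (seed × anchor) checks and required to be at
least 90%. Counting per check rather than AND-ing the two anchors within a
seed is deliberate: each check succeeds with ~95% probability by CI
calibration, so the per-check rate has a comfortable margin over the 90%
requirement, whereas the AND-ed version would sit exactly at its own
expected value and fail a well-calibrated implementation about a third of
the time. The same runs check FM/SEM concordance (mean log10 ratio within
±0.05) and the power of the depth-trend ANOVA (p < 0.01 in ≥ 95% of
seeds). These sizes — 2 400 cells per study, 20 seeds, 500 bootstrap
replicates — give the bootstrap and binomial margins quoted above while
keeping the full suite in the tens of seconds; they are stated here as the
package's test design.

## Degenerate inputs and error taxonomy

Non-positive or non-finite dimensions, negative THAA, shrinkage outside
[0, 1), inflation below 1, fractions not summing to 1 (tolerance 10⁻⁶),
empty samples, and schema violations (missing columns, AFM rows without a
height, heights on non-AFM rows, unknown modalities) all raise classed
conditions (`invalid_measurement_error`, `configuration_error`,
`degenerate_sample_error`, `schema_error`, …) with row numbers where
applicable. Extraction efficiencies above 100% are returned with a warning
rather than an error, since independent numerator and denominator counts
can legitimately cross 100%. Identical ANOVA groups yield F = 0 with p
reported as 1.

## Known limitations

* Correction factors derive from cultured reference cells; deep-biosphere
  cells with lower water content may shrink less, so corrected SEM volumes
  could be biased high. The factors are config-overridable for exactly
  this reason.
* The carbon scaling assumes a fixed amino-acid-carbon share across
  depths; only the 0.40/0.55/0.75 presets probe this.
* Carbon density combines a per-sample carbon content with FM-based mean
  volumes, inheriting both branches' biases multiplicatively.
* The pipeline consumes tabulated dimensions; image segmentation and halo
  detection on pixels are out of scope.
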