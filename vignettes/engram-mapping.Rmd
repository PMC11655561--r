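---
title: "Micro-topographic mapping of activated-neuron ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-topographic mapping of activated-neuron ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engramap)
```

## The problem

Pharmacological disruption of fear-memory reconsolidation is usually read
out twice: behaviorally, as reduced freezing to the conditioned tone, and
anatomically, as a reduced number of activation-marker-positive neurons
(e.g. pERK⁺ cells) in the lateral amygdala. The anatomical readout carries
spatial information that a single total count throws away: the memory trace
is thought to live in small, spatially consistent ensembles — hotspots — so
the interesting question is *which sub-regions* a treatment silenced.
`engramap` implements that micro-topographic analysis as a tested pipeline,
together with the behavioral statistics of the accompanying freezing data
and a synthetic-data generator that makes every error rate of the pipeline
measurable.

## Binning model

Each animal contributes a point pattern: the (x, y) positions, in µm, of
marker-positive neurons inside a hand-traced ROI contour, with all sections
assumed pre-registered to a common reference frame. The contour's
axis-aligned bounding box is tiled into `rows × cols` equal rectangular
bins. Conventions, chosen so that every point maps to exactly one bin and
no point is silently lost:

* Bins are half-open, `[x0 + (c−1)w, x0 + cw) × [y0 + (r−1)h, y0 + rh)`,
  with the final row/column closed on the far edge.
* Point-in-polygon is **boundary inclusive** (even–odd ray casting with an
  explicit on-edge test): a neuron recorded exactly on the traced contour
  counts. This convention is part of the method's contract, which is why
  the test is implemented here rather than delegated; the test suite
  verifies it against an independent library implementation away from the
  boundary, where conventions cannot differ.
* A bin belongs to the analysis family iff its *centre* is inside the
  contour (centre-in-polygon rather than area-overlap: deterministic, and
  matching how a rectangular matrix is visually superimposed on a traced
  contour). Grid defaults are 7 × 9 = 63 bins — a family size that gives
  several expected neurons per bin at realistic totals — and
  `suggest_bin_dims()` helps pick dimensions targeting ≥ 1 expected neuron
  per bin for other densities.
* An in-ROI point can fall in a bin whose centre lies *outside* the
  contour. Such points stay in their geometric bin (conservation over all
  bins is exact); the bin itself is masked from statistics, and the number
  of points it swallowed is reported per animal (`n_in_masked_bins`), so
  the discrepancy is visible rather than silent.

Raw counts, not area-normalized densities, feed the statistics: all bins
have equal area, so normalization would only rescale every test identically.
Group density maps are per-bin means across animals; coefficient-of-variance
maps are per-bin sample SD (n − 1 denominator, since groups are small
samples, typically n = 6) divided by the mean, flagged undefined where the
mean is zero.

## Per-bin statistics and FDR

Each family bin is tested with a one-way fixed-effects ANOVA across groups,
animals as replicates. Count data at n = 6 per group hit degenerate cases
regularly, so the conventions are explicit rather than incidental:

* all values equal across groups → `F = 0, p = 1`;
* zero within-group variance with unequal means → `F = ∞, p = 0`;
* bins in which *no* animal has a neuron are structurally empty and are
  excluded from the family entirely — testing them would only inflate the
  multiplicity burden `m`.

The family of p-values is corrected by the Benjamini–Hochberg step-up
(`q₍ᵢ₎ = min₍ⱼ≥ᵢ₎ p₍ⱼ₎ m / j`, capped at 1), with the tolerable limit
`q < 0.1` by default. The full q-matrix is reported, including values above
the threshold, for visualization. The step-up is authored in the package —
it is the core of the q-matrix construction — and the test suite holds it
to exact agreement with a literal brute-force implementation of the
definition and to `stats::p.adjust(..., "BH")`.

Within each FDR-significant bin, *planned* pairwise comparisons locate the
effect: pooled-variance two-sample t-tests (Welch by flag) of each
treatment versus the reference and between treatments, uncorrected at
α = 0.05. Uncorrected pooled t inside FDR-gated bins is a documented design
choice: the comparisons are planned and conditional on the omnibus
rejection, and the gate already controls the family-wise discovery rate.
Codes follow the hotspot-attribution logic: `all-drugs-lower` when every
treatment is significantly below the reference and no two treatments
differ; `<group>-specific` when one treatment is below the reference *and*
below every other treatment; `other` otherwise; `none` for non-significant
bins.

A whole-ROI comparison (`total_count_anova()`) runs the same one-way ANOVA
on per-animal totals over the family bins, the coarse statistic the
topographic analysis refines.

## Behavioral statistics

**Inclusion.** Animals that froze ≤ 37% at memory reactivation failed to
acquire the conditioned memory and are excluded before analysis. The
criterion is *strictly greater than*: an animal at exactly 37.0% is
excluded.

**Mixed ANOVA.** Freezing is analysed with the textbook two-way mixed
partition: treatment (between-subject) tested against subjects-within-groups
(df `N − k`); day and treatment × day (within-subject) tested against the
within-subject residual (df `(N − k)(m − 1)`). Published reports in this
literature sometimes print other denominator degrees of freedom (e.g. a
pooled residual for all three effects); the package deliberately implements
the standard partition and documents the df it uses, rather than
reverse-engineering an unstated pooling convention. The implementation is
validated against `aov()` with an `Error()` stratum and against hand-summed
toy tables.

**Post-hoc.** Tukey HSD (studentized range, Tukey–Kramer for unequal n)
compares groups on subject means, using the between-subject error term —
group is a between-subject factor, so that is its correct error. The
degenerate-data conventions (zero error variance) mirror the per-bin ANOVA
for cross-module consistency.

**Power.** `rm_anova_power()` implements the noncentral-F formulations for
repeated-measures designs in the convention popularized by G*Power, with
Cohen's f on the total-variance scale and compound-symmetric correlation ρ:
between effect `λ = f²Nm/(1+(m−1)ρ)` with df `(k−1, N−k)`; within and
interaction effects `λ = f²Nmε/(1−ρ)` with df `((m−1)ε, (N−k)(m−1)ε)` and
`((k−1)(m−1)ε, (N−k)(m−1)ε)`. The *between* formulation is the default: a
sample-size calculation for a drug effect concerns the between-group
factor, and with `f = 0.58, α = 0.05, power = 0.8, k = 6, m = 3, ρ = 0.5,
ε = 1` it yields a total N of 36 (power 0.870 at 36, 0.772 at 30) — the
only one of the three formulations whose smallest qualifying multiple of 6
is 36 rather than 42 (interaction-df hybrid) or 18 (within/interaction).
The Monte-Carlo agreement test simulates the matching generative model
(group shifts with population SD `f·σ` on the total scale, subject effects
with variance `ρσ²`) and checks the rejection rate of the package's own
mixed ANOVA against the formula within ±0.03. ε defaults to 1 (sphericity),
appropriate when no sphericity correction is applied downstream.

```{r power}
spec <- power_spec(f = 0.58, alpha = 0.05, power = 0.8, k = 6, m = 3, rho = 0.5)
rm_anova_sample_size(spec)
```

## The synthetic generator

`simulate_neuron_maps()` draws each animal's point pattern from an
inhomogeneous Poisson process: a uniform baseline over the ROI (rejection
sampling from the bounding box, with a 10⁶-proposal cap so pathological
polygons fail loudly) superposed with isotropic Gaussian hotspot components
truncated to the ROI. The per-animal total is Poisson with mean
`baseline_count + hotspot_multiplier × Σ amplitudes`; group structure
enters only through the multiplier, encoding "treatment erased the
localized activation" as a multiplier < 1. This is the simplest point
process with controllable localized effects, matching an analysis that
reduces positions to bin counts. `simulate_freezing()` draws percent
freezing Normal(mean, SD) per phase and clamps to [0, 100] — truncation
after sampling, since freezing is a bounded percentage.

Determinism: each animal's draw uses a sub-seed from a fixed-stride counter
scheme (`seed + 97003·i`, offset for the freezing stream), so identical
configurations are bit-identical, regenerating one animal is stable, and
the caller's RNG state is untouched.

Defaults (`demo_sim_config()`): 6 arms × 6 animals mirroring a typical
six-arm reconsolidation design (vehicle, three doses of a MEK inhibitor, a
positive and a negative control), baseline 250 neurons per animal, three
hotspots of amplitude 25–40 with effective treatments at multipliers
0.25–0.35. Freezing defaults — training-post 45%, reactivation 65%, test
60% (controls) vs ~30% (effective arms), SD 12 — are qualitative choices of
plausible magnitudes for auditory fear conditioning; published values for
such experiments appear only in figures, so these defaults are illustrative
rather than fitted. With reactivation at 65 ± 12, the > 37% inclusion
filter excludes about 1% of animals, exercising the filter without
decimating cohorts.

What the generator deliberately does *not* emulate: section-to-section
registration error, anisotropic or contour-hugging hotspot shapes,
over-dispersion beyond Poisson (litter or batch effects), counting errors,
and correlation between an animal's anatomy and its behavior. Passing
calibration tests therefore demonstrates that the *statistical machinery*
controls its error rates under the assumed model — not that real histology
satisfies those assumptions.

## Calibration experiments in the test suite

All are seeded and run at desk scale; sizes were chosen to keep Monte-Carlo
error well inside the asserted bands.

* **Null FDR.** 500 simulated cohorts, 6 groups × 6 animals, baseline 300,
  no hotspots, 63-bin family over a rectangular ROI (so the family is the
  full grid). Every rejection is false, so the empirical FDR is the
  frequency of any rejection; BH guarantees ≤ 0.1 under independence and
  the suite asserts ≤ 0.13.
* **Hotspot recovery.** A single tight hotspot (radius 20 µm, centred in a
  bin) with amplitude `A = 1 + √(1 + 4μ)`, the solution of
  `A/√(μ + A/2) = 2`, i.e. a standardized difference of 2 between
  hotspot-bearing and hotspot-free groups at the bin level. Design choice,
  made by an a-priori power calculation: with n = 6 per group, a two- or
  three-arm layout cannot reach 80% recovery at that effect under a 63-bin
  BH threshold, while a six-arm layout (hotspot present in reference and
  negative control, erased in four treatment arms) has analytic power
  ≈ 0.85–0.9; the suite asserts ≥ 80% recovery over 300 simulations, and
  checks classification on a three-arm layout with a treatment-specific
  reduction, conditional on FDR significance.
* **Mixed-ANOVA calibration.** Type-I error of the group test at α = 0.05
  over 1,000 null cohorts (asserted within ±0.02) and Monte-Carlo power at
  the six-arm design spec over 2,000 replicates (asserted within ±0.03 of
  the noncentral-F value, 0.870).

## Known limitations

* Centre-in-polygon masking makes the family size sensitive to grid
  placement for bins straddling the contour; the masked-bin point counts
  are reported so users can judge the leakage.
* No spatial smoothing, cluster-extent inference, or permutation maxT
  correction: bins are treated as exchangeable univariate tests, which
  ignores spatial autocorrelation of real ensembles.
* The mixed ANOVA assumes compound symmetry; no Greenhouse–Geisser
  correction is applied (ε enters only the power module).
* Planned comparisons are uncorrected by design; users wanting familywise
  control inside bins should lower `alpha`.
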