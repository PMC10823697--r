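---
title: "Quantifying colony-overlay screens and ABTS kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying colony-overlay screens and ABTS kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abtsscreen)
```

## The measurement problem

Colony-array overlay assays report secreted enzyme activity as a colorimetric
stain around each colony site: an agarose overlay containing ABTS is poured
over the membrane after the colonies are washed off, the enzyme left on the
membrane oxidizes the substrate, and the green-blue radical product (A420)
darkens each site in proportion to local activity. Two systematic artifacts
stand between the photograph and a per-strain activity estimate:

* an uneven **background illumination** of the membrane itself, and
* an **edge artifact** — sites near the plate periphery stain more strongly
  than equally active sites near the center, in a pattern that follows
  concentric rectangles rather than single rows or columns.

`abtsscreen` implements the full chain from image to replicate-supported hit
call, the matching quantification of liquid kinetic assays, and a synthetic
generator that produces all of these data with known ground truth.

## Densitometry model

An image enters as the photographed intensity field in `[0, 1]` (stage
`"raw"`), is inverted so that product signal is positive, corrected by a
background illumination function, and reduced to one mean intensity per grid
site:

1. **Inversion**: `1 - intensity`; RGB input is collapsed to grayscale with
   Rec. 709 luma weights first.
2. **Background illumination function** (`estimate_background()`): on each
   inverted blank plate the minimum pixel intensity is taken per 5 × 5-pixel
   block (partial edge blocks are truncated rather than dropped, so the
   field covers the full image); block minima are combined across the blank
   set by **elementwise minimum**; the block field is upsampled to pixel
   resolution; and a square median smoothing filter (radius 7 px by default)
   removes bright or dim imaging artifacts. Combining blanks by minimum and
   the filter window size are choices of this package — the minimum is the
   conservative combination (the background can only be *at most* the
   dimmest observation at a location), and radius 7 comfortably spans the
   5-pixel block structure while remaining far smaller than a colony. Both
   are configurable; sensitivity to the combination rule can be probed by
   passing a single blank at a time. The median filter operates on the
   16-bit intensity scale (matching the image bit depth), so constant
   regions are reproduced to within 1/65535.
3. **Subtraction** clamps at zero: intensities are physical signal, and a
   negative corrected intensity carries no information.
4. **Site measurement** (`measure_sites()`): the mean over pixels whose
   centers lie within `circle_diameter / 2` (Euclidean distance, inclusive)
   of the site center. The 101-px default circle matches the screen's
   quantification geometry; grid placement comes from an explicit
   `grid_spec()` — automatic grid registration is out of scope. The circle
   membership rule is deliberately simple enough to verify against a naive
   double loop over pixels, and the test suite does exactly that.

Manual growth flags (1 = normal, 0 = no/abnormal growth) enter as a table;
sites absent from the table default to 1, since manual flagging is the
exception workflow. Flag-0 sites keep their measured intensity but are
excluded from every median and from hit calling.

## Plate scoring

**Normalization.** Site intensities are divided by the plate median taken
over flag-1 sites, making plates comparable without any global rescaling;
the flag-1 median of normalized values is exactly 1. The median of an even
count is the mean of the two central order statistics throughout.

**Zone correction.** Zones are concentric rectangular rings indexed from the
periphery: a site at 0-based position (r, c) on an `R x C` grid belongs to
ring `min(r, c, R-1-r, C-1-c)`, and with the default `zone_width = 1` each
ring is its own zone (a 16 × 24 grid has 8 zones). If a zone's flag-1 median
of normalized values exceeds 1.0 — strictly; a zone sitting exactly at the
plate median is left alone — every value in the zone (including flag-0
sites) is divided by that zone median. The correction therefore never
increases a value, and it is idempotent: after division the zone's flag-1
median is 1. Ring width 1 is the finest spatial resolution the artifact
geometry supports; wider rings are available for sparser plates.

**Modified Z-scores.** Per plate, over flag-1 zone-corrected values:
`MAD = 1.4826 * median(|x - median|)`, `z = (x - median) / MAD`. The MAD is
a robust scale estimate, so a few genuinely strong secretors do not inflate
the denominator and mask themselves. A plate with `MAD = 0` (degenerate,
e.g. constant intensities) is an error, not a silent zero-division.

**Hit calling.** Positive: `z >= z_threshold` (default 2.5) in at least
`min_replicates` (default 2) replicates; negative: the mirrored rule at
`z <= -z_threshold`. The negative rule mirrors the positive one because
reduced-activity strains are identified the same way on the other tail; the
threshold and replicate count are configurable. A strain qualifying on both
sides across replicates is internally inconsistent and is called `none`
with a warning. Flag-0 replicates never support a call.

## Kinetic quantification

**Linear-range trimming** (`fit_linear_range()`): OLS on the retained
points, removing one end point at a time until the Pearson correlation
coefficient reaches `r_min = 0.999`; once reached, end points keep being
removed while removal strictly improves r. The refinement means a noiseless
saturating trace is trimmed back to exactly its linear segment (the fitted
slope then matches the construction to machine precision), while on noisy
data it typically removes at most one extra point before r stops improving.
Only end points are candidates — nonlinearity in these assays is saturation
(late) or lag (early), so interior points are never dropped. The default
`trailing_first` strategy prefers the trailing end, falling back to the
leading end; `best_improvement` always drops whichever end helps r more.
`min_points = 5` floors the retained count so the procedure cannot walk down
to a two-point "perfect" fit. Pearson r (not R²) implements the correlation
criterion; since r² of a simple regression is the squared Pearson r, an R²
semantics can be matched by passing `r_min = sqrt(0.999)`.

**Beer–Lambert conversion** (`activity_from_slope()`):
`activity = slope / (epsilon * path_length) * reaction_volume * 1e6`
µmol/min. Defaults: ε = 36,000 M⁻¹cm⁻¹ (literature value for the oxidized
ABTS radical at 420 nm), path length 0.58 cm (the liquid depth of 200 µL in
a standard flat-bottom 96-well), reaction volume 2 × 10⁻⁴ L. These are
stated explicitly because absolute activities depend on them entirely;
fold changes and significance calls do not, which is why only relative
quantities should be compared across laboratories. Activity is reported per
reaction well by default; `per_supernatant = TRUE` rescales by the
reaction-to-supernatant volume ratio (10× under the default 20 µL
supernatant input).

**Normalization and fold change**: `activity / OD600` per replicate;
`fold_change` is the ratio of strain mean to reference-strain mean
normalized activity within the same assay grouping.

**Comparison statistics.** Dunnett's many-to-one comparisons are computed
from the one-way ANOVA via the multivariate-t distribution (multcomp); the
quasi-Monte-Carlo integration runs under a fixed local seed (restoring the
caller's RNG state) with integration controls targeting an absolute error
of 10⁻³ — ample for decisions at the 0.05/0.01/0.005 cutpoints. Tukey's
all-pairs comparisons use the studentized-range distribution and are fully
deterministic. The test suite cross-checks both against an independent
Monte-Carlo null of the max-|t| (resp. studentized-range) statistic at 10⁵
draws, so the adjusted p-values never rest on a single implementation.
Relative transcript levels use the standard ΔΔCt rule, `2^-ΔΔCt`.

## What the synthetic data emulate — and what they do not

The generator produces the study conditions the pipeline is designed for:

* **Plate images**: colonies as uniform disks (Gaussian edge blur, σ = 1 px)
  on a 16 × 24 lattice; per-site disk amplitude
  `base_signal × effect × (1 + edge_amplitude × zone_factor) × site_noise`.
  The edge artifact is **multiplicative** and shaped by the concentric-ring
  index (linear from 1 at the outermost ring to 0 at the center), i.e.
  exactly the geometry the zone correction targets — the simulator must
  produce the artifact the correction is built for, and its amplitude
  (default 0.3) is a free parameter since no quantitative description of
  the real artifact exists. Per-site noise (`signal_cv`, default 0.1)
  models colony-to-colony biological variation; per-pixel Gaussian noise
  (`noise_sd`, default 0.01) models imaging noise. The background field is
  a smooth, config-deterministic gradient-plus-bump, identical across
  blanks and plates, peaking at `background_field_scale` (default 0.1).
* **Kinetic traces**: linear phase of the given slope, then an exponential
  approach to a plateau with a continuous first derivative (time constant
  `tau`, default 10 min). Substrate depletion kinetics are approximately
  exponential in this regime, and only the linear phase is ever analyzed,
  so the exact saturation form is immaterial to the estimates.
* **Activity studies**: replicate normalized activities drawn around
  `effect × reference_mean` with a given CV (default 0.1, a typical
  biological-replicate spread for such assays at n = 3), OD600 drawn
  independently (CV 0.05) and multiplied back so the raw table is
  internally consistent.

Not emulated: real colony morphology and size variation, agarose diffusion
halos, camera optics and vignetting, correlated spatial noise, plate-to-
plate background differences, or growth–secretion coupling. Passing the
recovery studies therefore demonstrates that the *computational chain* is
correct and well-calibrated under the stated noise model — not that the
assay itself has a given sensitivity on real plates.

## Reference experiments and problem sizes

Two simulation studies are shipped as package functions and re-run by
`scripts/acceptance.R`:

* `simulate_screen_study()`: 4 plates × 3 replicates at 384 sites (desk-
  scale stand-in for a 48-plate screen), 6 planted 3× positives per plate
  (24 total), site CV 10%, edge amplitude 0.3, 6 blank plates, full
  image-to-hits pipeline; reports sensitivity and false-positive count
  against ~1.5 × 10³ null strains. The base signal is lowered to 0.15 so a
  3× effect under the edge artifact stays below clipping.
* `liquid_validation_study()`: a synthetic stand-in for a liquid validation
  of overlay positives — 66 candidates in triplicate against a reference,
  17 carrying real effects above twofold (including planted folds 5.3, 5.0
  and 4.3, the remainder drawn in 2.2–3.5) and 49 drawn in 0.9–1.1,
  CV 0.1. At these settings the Dunnett-adjusted power for a twofold effect
  is essentially 1 while the familywise false-positive rate stays well
  below one expected call, so the planted/recovered significant count is
  stable across seeds. All of it is simulated; no measured data set is
  bundled.

`fold_recovery_study()` averages estimated folds over 100 simulated studies,
since a single n = 3, CV = 0.1 study estimates a fold only to ~±10%.

## Numerical conventions and degenerate inputs

* Grid indices are 0-based row-major internally; user-facing files are
  1-based with A1-style well names.
* All generators are pure functions of their parameters and a seed;
  pipeline drivers derive stage sub-seeds deterministically from one
  top-level seed.
* Subtraction clamps at 0; simulated images clip to `[0, 1]` before the
  16-bit write.
* Zone-correction idempotence is exact up to floating-point division
  (≤ 1 ulp per corrected zone); tests assert it at 10⁻¹².
* Errors, not guesses: all-flag-0 plates, zero plate medians, zero MAD,
  constant traces, unreachable `r_min` (the error names the best r
  achieved), negative slopes, missing OD600, and absent reference strains
  all fail loudly with context.

## Limitations

Grid placement must be supplied; there is no image registration, colony
segmentation, or colony-size quantification. Camera RAW decoding is out of
scope (convert to TIFF/PNG first). The zone correction assumes the
concentric-rectangle artifact geometry; row/column polish corrections and
LOESS-type spatial smoothing are intentionally not provided. Absolute
activities inherit the uncertainty of ε and path length; cross-study
comparisons should use fold changes.
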