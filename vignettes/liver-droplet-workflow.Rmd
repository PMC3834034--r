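---
title: "Quantifying hepatic lipid droplets and their molecular correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hepatic lipid droplets and their molecular correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liverLD)
```

## What this package models

Studies of liver lipid metabolism in growth-restricted (low birth weight)
pigs quantify hepatic fat storage by Oil Red O histology: neutral lipids in
frozen liver sections take up the red lysochrome, and intracellular lipid
droplets (LD) appear as red, approximately circular profiles. Because the
red stain absorbs green light, droplets are *dark in the green channel* of
an RGB micrograph — this polarity is fixed throughout the package and
deliberately not configurable, so it cannot be silently inverted.

`liverLD` implements the four computational stages such a study runs:

1. **Droplet segmentation** (`segment()`): green-channel extraction,
   percentile contrast rescaling, thresholding, and rule-based artifact
   removal, producing an integer-labeled mask on a calibrated pixel grid.
2. **Morphometry** (`measure_droplets()`, `summarize_field()`,
   `group_summary()`, `group_fold_changes()`): per-droplet area, equivalent
   diameter, circumference, convex area and centroid in micrometre units;
   nearest-neighbour spacing; field, animal and group aggregation; spherical
   volume estimates and group fold changes.
3. **Promoter methylation analysis** (`permutation_test()`,
   `validate_amplicons()`): a label-reassignment significance test on
   per-CpG methylation ratios, plus a coordinate audit of the bisulfite
   amplicon definition table bundled with the package.
4. **Expression selection and group statistics** (`quantile_normalize()`,
   `de_test()`, `select_genes()`; `two_way_anova()`,
   `percent_deviation_table()`): the microarray gene-list stage and the
   phenotype statistics (balanced two-way ANOVA for birth weight × feed
   restriction with a normality gate, Bonferroni post-hoc tests and
   percent-deviation contrast tables).

Because the original micrographs of such studies are typically not
deposited, every stage is exercised against **synthetic data with known
ground truth** (`generate_section_image()`, `generate_methylation_table()`,
`generate_expression_matrix()`). The numbered scripts under `analysis/`
run the whole workflow end to end.

## The synthetic section generator

`synthetic_image_spec()` describes a field: anti-aliased disks in a droplet
colour over a uniform background, lognormal radii (median in µm and
log-scale sigma), optional per-channel Gaussian noise, and optional
artifacts. Ground truth records analytic centres and radii; the analytic
disk area πr² and the rasterized pixel count agree to within a one-pixel
boundary ring, which is why area-level contracts in the tests carry a ~5%
rasterization tolerance while algebraic identities (equivalent diameter vs
area, volume fold vs diameter fold) are asserted at machine precision.

Key conventions, chosen once:

* **Pixel calibration**: 0.5 µm/px by default. Microscope-specific
  calibration is a property of the instrument, not reconstructable from
  published summaries; 0.5 µm/px makes a sub-micrometre droplet span more
  than one pixel, so nothing physiologically plausible is sub-resolution.
* **Coordinates**: 0-based pixel grid, x rightward, y downward; physical
  coordinates are pixel index × pixel size at pixel centres.
* **Hardcore placement**: by default droplet centres must clear the sum of
  radii plus a 2 px guard margin, so anti-aliased rims never fuse and the
  ground-truth count equals the rendered object count. Placement is
  rejection sampling with an explicit attempt budget; exhausting it is an
  error, not a silent shortfall.
* **Artifacts** come in exactly two archetypes with crisp filter targets:
  elongated streaks (axis ratio ≥ 4, low circularity) and sub-resolution
  specks (area < 4 px).

What the generator does *not* emulate: tissue texture, nuclei, uneven
illumination, staining chemistry, overlapping or touching droplets, and 3-D
section effects. Passing tests therefore demonstrate the correctness of the
measurement chain, not segmentation performance on real histology.

## Segmentation: replacing interactive steps with rules

The original microscope macro relied on an operator to pick the threshold
and delete false objects. For reproducibility both steps are automated:

* **Threshold**: exhaustive between-class-variance (Otsu) search over all
  256 candidate levels; droplets are the low-intensity class, so the
  foreground is everything strictly below the effective threshold. A fixed
  threshold mode is kept for parity experiments. A constant image cannot be
  auto-thresholded: `otsu_threshold()` raises an error advising fixed mode,
  while the composed `segment()` treats a perfectly uniform field as
  containing no objects.
* **Artifact filter**: connected components (8-connectivity, so the rims of
  round objects are never split) are removed when they fail the area bounds
  (defaults: min 4 px, max 10% of the field), fall below the minimum
  circularity 4πA/P² (default 0.3), or touch the field border (default
  policy: exclude). The filter is idempotent.

**Contrast rescaling** maps the `[contrast_low, contrast_high]` percentile
window linearly onto 0–255. The low anchor must sit *below* the stain area
fraction: if it lands in the background distribution, sparse droplets clip
to black while background noise is stretched across the full range, and the
between-class-variance criterion then splits the background instead of
isolating the droplets. The defaults (0.1, 99.9) are safe for stain
fractions above 0.1%; fields expected to contain no stain at all are
ill-posed for automatic thresholding and should use a fixed threshold.

**Perimeter estimator** (frozen; "circumference" in reports): the
crack-edge count — pixel edges facing a different label or the image border
— multiplied by π/4. This correction makes the estimator exact in
expectation over orientations for convex shapes and equal to 2πr for a
rasterized disk; for axis-aligned rectangles it underestimates by up to
21%, which is immaterial for circularity *filtering* (only a lower bound is
applied) but means circularity can exceed 1 for blocky shapes. Convex area
is the area of the convex hull of the pixel *squares* (not centres), so
`convex_area >= area` holds identically and convex pixel shapes have
`convex_area == area`.

Under the reference conditions (radii ≥ 3 px, hardcore placement), the
suite verifies perfect recovery on noiseless fields over 100 seeds and
≥ 95% precision and recall at noise sd 10 (8-bit units). Overlapping
droplets are excluded by construction; behaviour on touching objects is
undefined and no watershed splitting is attempted.

## Morphometry and the reporting chain

The aggregation hierarchy is fixed to match the study design: object →
field → animal (mean over that animal's 16 fields; the bundled workflow
uses 4 to stay light) → group (mean ± SEM over 3 animals). SEM is always
computed across animals — treating the 48 fields of a group as independent
would understate the error.

Spherical volume uses V = πd³/6 on the **group-mean equivalent diameter**
(matching single-value reporting practice; a mean-of-per-animal-volumes
mode is exposed but non-default). Two algebraic consequences are used as
self-checks and worked examples throughout:

* volume fold = (diameter fold)³, so a per-droplet volume ratio of
  0.248/0.176 implies a diameter increase of
  `r round(100 * (sphere_diameter_fold(0.248/0.176) - 1), 1)`%;
* with equal field areas, total-area fold = count fold × mean-size fold,
  and volume-per-total-area fold = count fold × volume fold
  (3.7 × 1.249 ≈ 4.6; 3.7 × 1.409 ≈ 5.2).

"Distance between neighbours" is interpreted as centroid-to-centroid
nearest-neighbour Euclidean distance — the standard, oracle-checkable
choice; edge-to-edge distance would differ by the radii and is not
implemented. Report-parity rounding is one decimal for folds and percents.

## The methylation permutation test

Quantitative bisulfite methylation pipelines yield a ratio in [0, 1] per
CpG unit and sample. The significance procedure reassigns samples to the
experimental and control groups and asks whether the observed group
difference persists — a *label permutation* scheme (despite sometimes being
called a bootstrap; no resampling with replacement is involved, and the
package names it accordingly). Decisions fixed here, because the procedure
is typically underspecified in publications:

* statistic: mean(experimental) − mean(control), two-sided via |difference|
  (one-sided modes exposed);
* exhaustive enumeration of all `choose(n, n1)` relabelings whenever that
  count is ≤ 10,000 (p-values are then exact rationals and seed-invariant);
  Monte-Carlo above the cap, with the observed labeling included in the
  null set so p ∈ [1/(N+1), 1];
* missing values: complete-case within site and group; a site with one
  group entirely missing is skipped with a warning;
* **attainable levels are reported explicitly**: with 3 samples per group
  there are only 20 relabelings and the observed split always ties its
  mirror image, so the smallest two-sided p is 0.1. Comparing such data
  against α = 0.05 silently would guarantee no discoveries; the default α
  is therefore 0.1 and the result object records the attainable minimum.

The bundled amplicon table (38 promoter amplicons across PTPRS, PPP1R3E,
SORT1, WNT5B, PDE9A, FGFR4, FABP5) uses gene-relative coordinates with no
position 0; the inclusive span is end − start + 1 on one side of the origin
and |start| + end across it. `validate_amplicons()` recomputes every span:
36 of 38 printed lengths are consistent, and two rows (PPP1R3E_amp07 and
FGFR4_amp26) disagree with every plausible convention — they are flagged
with warnings, never silently corrected, since the typo could equally be in
the coordinates or the length.

## Expression selection

Quantile normalization (via `limma::normalizeQuantiles`, ties receiving the
mean of the spanned quantile means) forces identical column distributions
and is idempotent. Tests run as Welch's unequal-variance t on log2
intensities; fold changes are computed on the linear scale and reported
with the mixed-sign convention (+r for up, −1/r for down), and the gene
list applies |FC| ≥ 1.3 and p ≤ 0.05, both inclusive. Two deliberate
interpretations, surfaced as configuration because the source descriptions
are ambiguous:

* "paired t-test with unequal variance" is self-contradictory; since
  cross-group animals are distinct individuals, the default is Welch
  (unpaired). A genuinely paired mode exists but requires an explicit
  pairing map.
* whether folds are linear- or log-scale is rarely stated; here tests are
  on log2, folds on linear, both documented and frozen in tests.

No multiple-testing correction is applied by default (matching
threshold-style gene lists); Benjamini–Hochberg is available by flag. An
optional complete-separation criterion (highest signal in one group at or
below the lowest in the other) mirrors the alternative selection rule used
for borderline persistent genes.

## Group statistics

Phenotype quantities are analysed with a balanced two-way ANOVA (birth
weight × diet); unbalanced input is rejected rather than silently switching
sums-of-squares types. The normality gate is a Shapiro–Wilk test at
α = 0.05 with natural-log transform on failure — the conventional
direction (pass = p > 0.05); published wordings sometimes state the
inequality backwards. Post-hoc contrasts use the residual mean square of
the fitted model with Bonferroni adjustment (family size = number of
requested contrasts), and the percent-deviation table prints the signed
percent only where the adjusted p ≤ α, a parenthesised value for trends
(0.05 < p ≤ 0.1), and the literal marker `ns` otherwise. Reductions are
negative, increases positive, one decimal.

## Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` run on deliberately compact
problem sizes chosen to exercise every contract while keeping the whole
suite in tens of seconds: 256–512 px fields with 15–50 droplets (radii
≥ 3 px), 100 seeds for recovery properties, 1,000 null CpG sites for
type-I calibration, 500 spiked transcripts for power, and 400 simulated
null 2×2 tables for the ANOVA chain. Equality tolerances are 1e-12 for
algebraic identities, ~5% for rasterization-level comparisons, and
3-sigma binomial bands for Monte-Carlo rates.

Degenerate inputs have documented behaviour rather than silent fallbacks:
constant images (no-op contrast, auto-threshold error / zero objects),
empty fields (count 0, undefined means flagged `NA`), fewer than two
objects (nearest-neighbour distance undefined, field flagged), zero
within-group variance (standard-error floor, flagged), empty design cells
(error naming the cell).

## Known limitations

* Real Oil Red O histology contains texture, illumination gradients and
  touching droplets that the generator does not model; performance numbers
  from synthetic recovery do not transfer to real slides.
* Droplet-free *noisy* fields are ill-posed for automatic thresholding:
  with nothing to separate, the threshold lands inside the noise and the
  rule-based filter removes most but not necessarily all speckle clusters.
* No stereological correction relates 2-D profile statistics to 3-D
  droplet size distributions; spherical volumes are descriptive estimates
  from mean profile diameters.
* The absolute scale of "volume per total LD area" depends on an
  unspecified reference field size; only its between-group fold is
  meaningful here.
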