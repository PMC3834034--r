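# liverLD

Lipid-droplet morphometry and molecular group statistics for liver
histology studies — a tested re-implementation of the computational
pipeline used in birth-weight / feed-restriction studies of hepatic lipid
storage in the pig.

Oil Red O stains neutral lipids red, so intracellular lipid droplets (LD)
appear as dark, round profiles in the green channel of an RGB micrograph.
`liverLD` automates the measurement chain around that observation and the
molecular analyses that accompany it:

* **Segmentation** — green-channel extraction, percentile contrast
  rescaling, automatic between-class-variance (Otsu) thresholding, and
  rule-based artifact removal (area bounds, circularity 4πA/P², border
  policy) on an 8-connected labeled mask.
* **Morphometry** — per-droplet area *A*, equivalent diameter
  *d* = 2√(A/π), circumference, convex area and centroid in µm; nearest-
  neighbour distances; field → animal → group aggregation (mean ± SEM
  across animals); spherical volume *V* = πd³/6 and group fold changes,
  with the identities *V*-fold = (*d*-fold)³ and total-area fold =
  count fold × size fold used as self-checks.
* **Promoter methylation** — a label-reassignment permutation test on
  per-CpG methylation ratios (exhaustive over all `choose(n, n1)`
  relabelings when feasible, exact rational p-values, attainable
  significance levels reported explicitly), plus a coordinate audit of the
  bundled 38-amplicon bisulfite primer table.
* **Expression selection** — quantile normalization, Welch tests on log2
  intensities, signed fold changes (+r / −1/r), and the |FC| ≥ 1.3 &
  p ≤ 0.05 gene-list filter.
* **Group statistics** — normality-gated balanced two-way ANOVA
  (birth weight × feed restriction), Bonferroni post-hoc contrasts, and
  percent-deviation tables with `ns` / trend markers.

Every stage is exercised on synthetic data with known ground truth
(section images with analytic droplet positions, methylation tables with
planted effects, expression matrices with spiked fold changes), generated
by the package itself.

## Worked example

```r
library(liverLD)

spec <- synthetic_image_spec(field_width_px = 384, field_height_px = 384,
                             n_droplets = 37, radius_median_um = 2.8,
                             noise_sd = 5, seed = 1)
sec <- generate_section_image(spec)
res <- analyze_section(sec)
res$mask
#> <labeled_mask> 37 objects (of 37 candidates) @ 0.5 um/px, threshold 127
round(res$summary[, c("count", "area_percent", "mean_size_um2",
                      "mean_diameter_um", "mean_nn_distance_um")], 2)
#>   count area_percent mean_size_um2 mean_diameter_um mean_nn_distance_um
#> 1    37         2.69         26.83             5.76               20.02
```

All 37 droplets are detected, covering 2.7% of the field with a mean
profile of 26.8 µm² (mean equivalent diameter 5.8 µm) and a mean
centre-to-centre nearest-neighbour spacing of 20.0 µm. Matching against
the generator's ground truth with
`match_to_ground_truth(res$features, sec$truth)` gives recall and
precision of 1.00 here.

The permutation test on a fully separated 3-vs-3 methylation fixture
returns its smallest attainable two-sided p:

```r
mm <- methylation_matrix(matrix(c(.05, .10, .15, .50, .55, .60), 1),
                         rep(c("experimental", "control"), each = 3))
permutation_test(mm)
#> <permutation_result> 1 sites, exhaustive over 20 relabelings (two.sided)
#>   alpha = 0.1; smallest attainable p = 0.1; 1 significant site(s)
```

## The analysis workflow

`analysis/01_simulate_data.R` … `05_group_statistics.R` run the full study
pipeline on synthetic data and write their tables under `results/`:
simulated U-like (low birth weight) and N-like sections, droplet
morphometry with group fold changes, the amplicon audit and methylation
permutation test, the expression gene list, and the ANOVA /
percent-deviation tables. Run them in order from the repository root:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

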