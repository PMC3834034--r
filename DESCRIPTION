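Package: liverLD
Title: Lipid Droplet Morphometry and Molecular Group Statistics for
    Liver Histology Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of the computational analyses used
    in birth-weight / feed-restriction liver studies in the pig: Oil Red O
    lipid-droplet segmentation (green-channel extraction, contrast
    enhancement, between-class-variance thresholding, rule-based artifact
    removal) and droplet morphometry (area, equivalent diameter,
    circumference, convex area, nearest-neighbour distances, spherical
    volume estimates and group fold changes); a label-reassignment
    permutation test for promoter CpG methylation ratios together with an
    audit of amplicon coordinate tables; microarray quantile normalization,
    Welch testing and signed fold-change gene selection; and balanced
    two-way ANOVA group statistics with a normality gate, Bonferroni
    post-hoc tests and percent-deviation contrast tables. Ground-truth
    bearing synthetic data generators (stained-section images, methylation
    tables, expression matrices) make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    limma,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
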