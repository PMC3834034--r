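#!/usr/bin/env Rscript
# Step 1 -- simulate the study's raw materials with known ground truth:
# stained-section images for a low-birth-weight-like (U) and a normal-like
# (N) group, a promoter methylation table with effects confined to two
# amplicons, and an expression matrix with spiked fold changes.
#
# Group image parameters encode the reported morphology: U fields carry
# 3.7x the droplet count and 1.121x the droplet diameter of N fields.

suppressPackageStartupMessages(library(liverLD))
dir.create("results", showWarnings = FALSE)
dir.create("results/sections", showWarnings = FALSE)

groups <- list(
  U = list(n_droplets = 37L, radius_median_um = 2.5 * 1.121),
  N = list(n_droplets = 10L, radius_median_um = 2.5)
)
n_animals <- 3L
n_fields <- 4L   # fields per animal (the full study protocol uses 16)

manifest <- list()
for (g in names(groups)) {
  for (a in seq_len(n_animals)) {
    for (f in seq_len(n_fields)) {
      seed <- 10000L * match(g, names(groups)) + 100L * a + f
      spec <- synthetic_image_spec(
        field_width_px = 384L, field_height_px = 384L,
        n_droplets = groups[[g]]$n_droplets,
        radius_median_um = groups[[g]]$radius_median_um,
        radius_sigma_log = 0.1, noise_sd = 5, n_artifacts = 2L, seed = seed
      )
      sec <- generate_section_image(spec)
      stem <- sprintf("results/sections/%s_a%d_f%d", g, a, f)
      write_section_image(sec, paste0(stem, ".tif"))
      write_ground_truth(sec, paste0(stem, "_truth.csv"))
      manifest[[length(manifest) + 1L]] <- data.frame(
        group = g, animal = paste0(g, a), field = f,
        image = paste0(stem, ".tif"), truth = paste0(stem, "_truth.csv"),
        pixel_size_um = spec$pixel_size_um,
        field_area_um2 = sec$field_area_um2, seed = seed)
    }
  }
}
manifest <- do.call(rbind, manifest)
write.csv(manifest, "results/section_manifest.csv", row.names = FALSE)
cat(sprintf("Simulated %d sections (%d groups x %d animals x %d fields)\n",
            nrow(manifest), length(groups), n_animals, n_fields))

meth <- generate_methylation_table(
  60, 3, effect_sites = 1:10, effect_size = 0.3, noise_sd = 0.05, seed = 77,
  site_ids = c(sprintf("FGFR4_amp04_CpG_%d", 1:5),
               sprintf("PTPRS_amp09_CpG_%d", 1:5),
               sprintf("PTPRS_amp03_CpG_%d", 1:25),
               sprintf("FABP5_amp09_CpG_%d", 1:25)))
write.csv(meth$values, "results/methylation_ratios.csv")
write.csv(data.frame(sample = colnames(meth$values), group = meth$groups),
          "results/methylation_groups.csv", row.names = FALSE)
cat("Simulated methylation table: 60 CpG sites x 6 samples,",
    "10 true effect sites (FGFR4_amp04 + PTPRS_amp09)\n")

expr <- generate_expression_matrix(5000, 3, n_spiked = 50, true_fc = 2,
                                   noise_sd_log2 = 0.144, seed = 78)
write.table(data.frame(transcript = rownames(expr$values), expr$values),
            "results/expression_matrix.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.csv(data.frame(sample = colnames(expr$values), group = expr$groups),
          "results/expression_groups.csv", row.names = FALSE)
writeLines(attr(expr, "spiked"), "results/expression_spiked_truth.txt")
cat("Simulated expression matrix: 5000 transcripts x 6 samples,",
    "50 spiked at fold 2\n")
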