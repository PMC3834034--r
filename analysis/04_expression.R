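#!/usr/bin/env Rscript
# Step 4 -- microarray stage on the simulated intensities: quantile
# normalization, Welch tests on log2 intensities, and the signed
# fold-change >= 1.3 & p <= 0.05 gene list.

suppressPackageStartupMessages(library(liverLD))

em <- read_expression_tsv("results/expression_matrix.tsv",
                          "results/expression_groups.csv")
res <- run_expression_selection(em, fc_threshold = 1.3, p_threshold = 0.05)

write.table(res$tests, "results/expression_tests.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(res$selected, "results/deg_selected.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

truth <- readLines("results/expression_spiked_truth.txt")
hit <- truth %in% res$selected$transcript
n_false <- sum(!res$selected$transcript %in% truth)
cat(sprintf("Selected %d transcripts (%d up, %d down) of %d\n",
            nrow(res$selected), sum(res$selected$direction == "up"),
            sum(res$selected$direction == "down"), nrow(res$tests)))
cat(sprintf("Spike recovery: %d/%d true fold-2 transcripts selected (power %.2f)\n",
            sum(hit), length(truth), mean(hit)))
cat(sprintf("False selections among %d nulls: %d (%.1f%% vs 5%% nominal per-test level)\n",
            nrow(res$tests) - length(truth), n_false,
            100 * n_false / (nrow(res$tests) - length(truth))))
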