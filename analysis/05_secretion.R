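#!/usr/bin/env Rscript
# Stage 5: multiplex plate preprocessing (below-range imputation, ln and
# z transforms), sample correlation, hierarchical clustering, PCA, and
# single-cell secretor classification.

suppressMessages(library(tmequant))

plate <- read_secretion_csv("results/run/plate.csv")
cat(sprintf("Plate: %d samples x %d analytes, %d below-range readings\n",
            nrow(plate$conc), ncol(plate$conc), sum(plate$censored)))

imp <- impute_oor(plate)
z <- transform_secretion(imp, "zscore")
write_secretion_csv(imp, "results/plate_imputed.csv")

cl <- cluster_profiles(z, k = 2)
cat("Sample dendrogram cut at 2 clusters:\n")
print(table(cl$row_clusters))

pca <- pca_scores(z, 2)
cat(sprintf("PC1/PC2 explained variance: %.0f%% / %.0f%%\n",
            100 * pca$explained[1], 100 * pca$explained[2]))
write.csv(data.frame(sample = rownames(pca$scores), pca$scores),
          "results/pca_scores.csv", row.names = FALSE)

cm <- correlation_matrix(transform_secretion(imp, "ln"))
write.csv(data.frame(sample = rownames(cm), cm),
          "results/sample_correlation.csv", row.names = FALSE)

sc <- simulate_single_cell_secretion(sim_config(seed = 1))
cls <- classify_secretors(sc$matrix, sc$thresholds)
cat(sprintf("Single-cell secretor fraction: %.2f (%d of %d cells)\n",
            cls$fraction, sum(cls$secretor), length(cls$secretor)))
cat(sprintf("Polyfunctional (>= 2 analytes): %.2f\n",
            cls$polyfunctional_fraction))
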