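#!/usr/bin/env Rscript

# Stage 5: principal component analysis of the 19 bioclim-style climate
# variables (correlation-matrix PCA; mixed degrees-C and mm units force
# standardization). The first three components are retained as the climate
# predictors for the path models.

library(conduitscaling)

climate <- readr::read_csv("results/data/climate.csv", show_col_types = FALSE)
pca <- fit_pca(climate)
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
readr::write_csv(tibble::as_tibble(pca$loadings, rownames = "variable"),
                 "results/tables/pca_loadings.csv")
readr::write_csv(
  tibble::tibble(component = seq_along(pca$explained_variance),
                 explained_variance = pca$explained_variance),
  "results/tables/pca_scree.csv"
)

print(pca)
cat(sprintf("PC1 %.1f%%, PC2 %.1f%%, PC3 %.1f%% -> first three PCs: %.2f%%\n",
            100 * pca$explained_variance[1], 100 * pca$explained_variance[2],
            100 * pca$explained_variance[3],
            100 * sum(pca$explained_variance[1:3])))
cat("Leading loadings on PC2 (temperature block dominates):\n")
print(round(sort(pca$loadings[, 2], decreasing = TRUE)[1:5], 2))
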