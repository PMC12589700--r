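#!/usr/bin/env Rscript

# Stage 6: phylogenetic path analysis. Four causal scenarios (null,
# indirect, direct, full) wire the three climate components, log
# distance-to-tip and each log trait; d-separation claims are tested by
# phylogenetic GLS, combined into Fisher's C and ranked by CICc, averaged
# over the candidate trees.

library(conduitscaling)

cfg <- run_config(
  traits = "results/data/traits.csv", trees = "results/data/trees.nwk",
  climate = "results/data/climate.csv", seed = 2026
)
paths <- run_paths(cfg)
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
readr::write_csv(paths$table, "results/tables/path_models.csv")

print(as.data.frame(paths$table), digits = 2)
for (nm in names(paths$details)) {
  cmp <- paths$details[[nm]]
  cat("\n", nm, "- mean CICc per scenario over",
      cmp$n_trees, "trees:\n", sep = "")
  print(as.data.frame(cmp$summary[, c("model", "q", "mean_C", "mean_CICc",
                                      "selection_rate")]), digits = 3)
}
cat("\n(the study was generated with climate acting on traits only through",
    "distance-to-tip, so indirect-route models should dominate)\n")
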