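#!/usr/bin/env Rscript
# Strongest/weakest link strata (top and bottom 10%, with the 1% core),
# per-module representation in the strata, and the gene-set table:
# per-state medians, paired Wilcoxon p-values, weighted-degree ratios and
# extreme-link counts for the planted module and its decoys.

library(oncorewire)

dir.create("results", showWarnings = FALSE)

layer <- readRDS("scratch/state_layer.rds")
gs <- read_gmt("scratch/data/sets.gmt")
states <- names(layer$weights)

extremes <- lapply(layer$weights, extreme_links)
landscapes <- lapply(layer$weights, detect_modules)
for (s in states) {
  rep_tab <- module_representation(extremes[[s]],
                                   discrete_assignment(landscapes[[s]]))
  write.table(rep_tab, sprintf("results/representation_%s.tsv", s),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
message("top-decile representation of the best-represented module per state:")
for (s in states) {
  rep_tab <- read.delim(sprintf("results/representation_%s.tsv", s))
  i <- which.max(rep_tab$top_decile)
  message(sprintf("  %s: module %s, ratio %.3f", s, rep_tab$module[i],
                  rep_tab$top_decile[i]))
}

tab <- pathway_report(gs, layer$ab, layer$net, layer$weights, extremes)
write.table(tab, "results/pathways.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab[, c("pathway", "n_in_network", "median_normal",
              "median_adenoma", "median_carcinoma",
              "p_normal_carcinoma")])
message(sprintf(
  "planted module: carcinoma median %.3f vs normal %.3f (wdeg ratio %.2f)",
  tab$median_carcinoma[1], tab$median_normal[1], tab$wdeg_ratio_carcinoma[1]))
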