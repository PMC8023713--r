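#!/usr/bin/env Rscript
# Weighted network diameter and average shortest-path length per state
# under the three directivity conventions (undirected / directed / mixed),
# after the negative-log probability-to-length mapping. The expected
# qualitative picture: the adenoma network is the least compact.

library(oncorewire)

dir.create("results", showWarnings = FALSE)

layer <- readRDS("scratch/state_layer.rds")
grid <- diameter_grid(layer$weights)
write.table(grid, "results/diameters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(grid[, c("state", "convention", "diameter", "avg_path_length")])

for (cv in unique(grid$convention)) {
  g <- grid[grid$convention == cv, ]
  message(sprintf("%-10s diameter ordering: %s", cv,
                  paste(g$state[order(g$diameter)], collapse = " < ")))
}
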