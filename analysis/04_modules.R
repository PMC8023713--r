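#!/usr/bin/env Rscript
# Overlapping-module landscapes per state (influence-function spreading,
# local-maximum hills, proportional merging), module naming by community
# centrality, cross-state module matching, and recovery of the planted
# module in the carcinoma landscape.

library(oncorewire)

dir.create("results", showWarnings = FALSE)

layer <- readRDS("scratch/state_layer.rds")
truth <- jsonlite::read_json("scratch/data/truth.json",
                             simplifyVector = TRUE)
states <- names(layer$weights)

landscapes <- lapply(layer$weights, detect_modules)
for (s in states) {
  land <- landscapes[[s]]
  da <- discrete_assignment(land)
  nm <- name_modules(land)
  message(sprintf("%s: %d modules (sizes %s); organizers: %s", s,
                  ncol(land$assignment),
                  paste(sort(table(da), decreasing = TRUE), collapse = ","),
                  paste(nm, collapse = " ")))
  write.table(data.frame(node = names(da), module = unname(da),
                         centrality = land$centrality[names(da)],
                         overlap_metrics(land, layer$weights[[s]])[-1]),
              sprintf("results/modules_%s.tsv", s),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

for (k in 1:2) {
  m <- match_modules(landscapes[[states[k]]], landscapes[[states[k + 1]]])
  write.table(m, sprintf("results/match_%s_to_%s.tsv",
                         states[k], states[k + 1]),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s -> %s: %d merge, %d split, %d stable",
                  states[k], states[k + 1],
                  sum(grepl("merge", m$annotation)),
                  sum(grepl("split", m$annotation)),
                  sum(m$annotation == "stable")))
}

jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
dac <- discrete_assignment(landscapes$carcinoma)
best <- max(vapply(colnames(landscapes$carcinoma$assignment), function(m)
  jac(names(dac)[dac == m], truth$planted), numeric(1)))
message(sprintf("best Jaccard of a carcinoma module vs the planted set: %.3f",
                best))
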