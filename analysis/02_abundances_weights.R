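#!/usr/bin/env Rscript
# From the simulated study files: quantile-normalize each state's
# expression, aggregate to per-gene abundances (pooled-sample medians),
# filter the network to measured genes / known types / giant component,
# and compute per-state link weights LW = log10(a_i * a_j) with their
# distribution summaries and pairwise paired Wilcoxon tests.

library(oncorewire)

dir.create("results", showWarnings = FALSE)

dat <- "scratch/data"
out <- "results"
states <- c("normal", "adenoma", "carcinoma")

net0 <- read_network(file.path(dat, "network.sif"))
ab <- abundance_table(setNames(lapply(states, function(s) {
  em <- read_expression(file.path(dat, sprintf("expr_%s.tsv", s)),
                        state_label = s)
  median_aggregate(list(quantile_normalize(em)))
}), states))
net <- filter_network(net0, rownames(ab))
message(sprintf("filtered network: %d -> %d nodes, %d -> %d edges",
                length(net0$nodes), length(net$nodes),
                nrow(net0$edges), nrow(net$edges)))

weights <- lapply(states, function(s)
  compute_link_weights(net, ab[, s], state = s))
names(weights) <- states

for (s in states) {
  e <- net$edges; e$weight <- weights[[s]]$weights
  write.table(e, file.path(out, sprintf("weights_%s.tsv", s)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  print(summarize_weights(weights[[s]]))
}

pairs <- combn(states, 2)
wil <- do.call(rbind, apply(pairs, 2, function(st) {
  r <- paired_wilcoxon(weights[[st[1]]]$weights, weights[[st[2]]]$weights)
  data.frame(state_a = st[1], state_b = st[2], W = r$statistic,
             p = r$p.value, n = r$n, method = r$method)
}, simplify = FALSE))
write.table(wil, file.path(out, "wilcoxon.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("paired Wilcoxon on per-edge weights:")
print(wil)

summ <- lapply(weights, function(w) {
  s <- summarize_weights(w)
  s[c("n", "median", "mean", "sd", "q1", "q3", "iqr", "min", "max",
      "bin_fractions")]
})
jsonlite::write_json(summ, file.path(out, "weight_summaries.json"),
                     auto_unbox = TRUE, digits = NA)
saveRDS(list(net = net, ab = ab, weights = weights),
        file.path("scratch", "state_layer.rds"))
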