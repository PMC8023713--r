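#!/usr/bin/env Rscript
# Generate the synthetic study standing in for the microarray compendium:
# a typed signaling network (edge-type mix modeled on the Human Cancer
# Signaling Network), three-state expression with a planted module that
# strengthens in carcinoma and gene-level variance inflation in adenoma,
# and gene sets (the planted module plus decoys). Writes everything under
# scratch/data/ in the plain-text formats the pipeline reads back.

library(oncorewire)

out <- "scratch/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = 1)
study <- generate_study(cfg)

write_network(study$network, file.path(out, "network.sif"))
for (s in names(study$expression)) {
  v <- study$expression[[s]]$values
  df <- data.frame(gene = rownames(v), v, check.names = FALSE)
  write.table(df, file.path(out, sprintf("expr_%s.tsv", s)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write_gmt(study$gene_sets, file.path(out, "sets.gmt"))
jsonlite::write_json(study$truth[c("planted", "hub")],
                     file.path(out, "truth.json"), auto_unbox = TRUE)

tab <- table(study$network$edges$type)
message(sprintf(
  "simulated %d nodes / %d edges (%s); planted module of %d around hub %s",
  length(study$network$nodes), nrow(study$network$edges),
  paste(names(tab), tab, sep = "=", collapse = ", "),
  length(study$truth$planted), study$truth$hub))
message("wrote network.sif, expr_{normal,adenoma,carcinoma}.tsv, sets.gmt, truth.json")
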