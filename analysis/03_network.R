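#!/usr/bin/env Rscript
# Step 3 — build the full disease-disease network (edge iff >= 1 shared
# associated SNP; edges annotated with shared SNP ids, counts and cosine
# similarity) and extract one egocentric network per ego-disease.

suppressMessages(library(egoddn))
dir.create("results", showWarnings = FALSE)

mat <- read_matrix("results/matrix.tsv")
phenos <- read_phenotype_info("results/cohort/phenotype_info.csv")

ddn <- build_full_ddn(mat, phenos)
write_network(ddn, "results/ddn.graphml", "graphml")
write_network(ddn, "results/ddn_edges.tsv", "edge_tsv")
cat(sprintf("full network: %d diseases, %d edges\n",
            nrow(ddn$nodes), nrow(ddn$edges)))

for (ego in reference_egos()) {
  net <- extract_ego_network(ddn, ego)
  write_network(net, sprintf("results/ego_%s.graphml", ego), "graphml")
  comp <- category_composition(net)
  cat(sprintf("ego %s: %d alters; categories: %s\n", ego,
              length(attr(net, "alters")),
              paste(sprintf("%s=%d", names(comp), comp), collapse = ", ")))
}
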