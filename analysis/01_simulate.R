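#!/usr/bin/env Rscript
# Step 1 — simulate the reference pleiotropic cohort.
#
# 5,000 individuals, 500 SNPs, 15 diseases; three ego-diseases (101-103)
# with planted causal overlaps of 10 SNPs (alters 104-106) and 5 SNPs
# (alters 107-112); the strong alters are hubs tied to background
# diseases 113-114. Writes the raw pipeline inputs under results/cohort/.

suppressMessages(library(egoddn))
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- reference_config(seed = 1L)
cohort <- simulate_cohort(cfg)
write_genotypes(cohort$genotypes, file.path(out, "genotypes.tsv"))
write_phenotype_info(cohort$phenotype_info, file.path(out, "phenotype_info.csv"))
write_causal_sets(cohort, file.path(out, "truth_causal_sets.tsv"))
writeLines(cohort$genotypes$person_ids, file.path(out, "cohort_ids.txt"))

stats <- association_scan(cohort)
write_summary_stats(stats, file.path(out, "summary_stats.tsv"))

diagnoses <- emit_diagnoses(cohort, seed = 2L)
write_diagnoses(diagnoses, file.path(out, "diagnoses.tsv"))

prev <- colMeans(cohort$disease_status)
cat(sprintf("simulated %d persons x %d SNPs x %d diseases\n",
            cfg$n_individuals, cfg$n_snps, cfg$n_diseases))
cat(sprintf("realized prevalence %.3f-%.3f (target %.2f)\n",
            min(prev), max(prev), cfg$prevalence))
cat(sprintf("%d association rows, %d diagnosis records\n",
            nrow(stats), nrow(diagnoses)))
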