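#!/usr/bin/env Rscript
# Step 5 — derive binary comorbidity labels from the diagnosis records:
# phi-correlation between the ego and each alter over the whole cohort;
# a pair is a true comorbidity iff phi > 0, p < 0.05 and C_ij > 0.

suppressMessages(library(egoddn))
diagnoses <- read_diagnoses("results/cohort/diagnoses.tsv")
cohort_ids <- readLines("results/cohort/cohort_ids.txt")

for (ego in reference_egos()) {
  net <- read_network(sprintf("results/ego_%s.graphml", ego), "graphml")
  truth <- label_alters(net, diagnoses, cohort_ids)
  write_truth(truth, sprintf("results/truth_%s.tsv", ego))
  cat(sprintf("ego %s: %d/%d alters are true comorbidities (phi %.3f-%.3f)\n",
              ego, sum(truth$is_comorbid), nrow(truth),
              min(truth$phi), max(truth$phi)))
}
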