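---
title: "Egocentric disease-disease networks: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Egocentric disease-disease networks: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Obstetric disorders — preeclampsia, placenta previa, gestational diabetes and
their relatives — are increasingly understood as windows onto a woman's
long-term disease risk. `egoddn` implements a network-medicine approach to
ranking candidate complications: diseases that share significantly associated
genetic variants are connected in a disease-disease network (DDN), and the
local neighbourhood of an index ("ego") disease is mined for likely
comorbidities by label propagation.

The pipeline has four stages:

1. **Preprocessing.** PheWAS summary statistics (one p-value per
   disease-variant pair) are filtered to significant, common, well-powered
   associations — p ≤ 1e-4 (inclusive), MAF ≥ 0.01, ≥ 200 cases — with
   male-specific phenotypes and PheCodes specified to the hundredth's place
   excluded, followed by per-phenotype LD pruning (dosage R² ≤ 0.2 within
   250 kb). The survivors form a binary disease × SNP matrix whose rows
   $v_i$ are the per-disease association vectors.
2. **Network construction.** Two diseases are connected iff they share at
   least one surviving SNP. Each edge stores the shared SNP ids, their
   count, and the cosine similarity
   $w_{ij} = v_i \cdot v_j / (\lVert v_i\rVert\,\lVert v_j\rVert)$.
   The egocentric network of an ego-disease is the induced subgraph on the
   ego plus all its neighbours (alter-diseases), alter-alter edges included.
3. **Scoring.** With $y$ equal to 1 on the ego and 0 elsewhere, the score
   vector minimizes $(f-y)^\top(f-y) + \mu f^\top L f$ with $L = D - W$ the
   graph Laplacian, giving the closed form $f = (I + \mu L)^{-1} y$. Scores
   are min-max normalized and alters stratified into recommendation
   quartiles.
4. **Validation.** Comorbidity ground truth comes from diagnosis records:
   the phi-correlation (Pearson correlation of the two binary disease
   indicators) between ego and alter, with a pair labelled a true
   comorbidity iff $\Phi > 0$, p < 0.05 and the joint count $C_{ij} > 0$.
   Egocentric scores are compared against full-network scores on the same
   alter sets by AUC and Spearman rank correlation; individual-level
   genotype data additionally tests whether carriers of the shared SNPs are
   enriched for the comorbidity (2 × 2 chi-squared).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `p_max` | 1e-4 | association significance cut (inclusive) |
| `maf_min` | 0.01 | minor-allele frequency floor |
| `min_cases` | 200 | case-count floor per phenotype |
| `ld_r2_max`, `ld_window_kb` | 0.2, 250 | LD pruning threshold and window |
| `mu` | 1.0 | propagation regularization; `mu -> 0` pins scores to the label, `mu -> Inf` flattens them to uniform |
| `weighting_ego` | cosine | edge weights for the egocentric solve |
| `weighting_full` | count | edge weights for the full-network baseline |

The propagation weight `mu` has no published reference value; 1.0 is the
neutral default and `analysis/04_score.R` reports rank stability of the
egocentric scores over `mu` in {0.1, 1, 10} (in the reference world the
ranking is invariant, Spearman rho = 1.0 across that range).

### Why count weights for the full-network baseline

The full DDN is defined with edge weights equal to the *number* of shared
SNPs, while the egocentric similarity $W'$ is defined as *cosine*
similarity. We follow that construction literally: the egocentric solve
uses cosine weights, the full-network baseline count weights. This matters:
restricted to the ego's alter set, a cosine-weighted full-network solve
produces an essentially identical alter ranking to the egocentric solve
(the only difference is mass leaking to distance-2 nodes and back), so the
two conditions could not meaningfully differ. Under count weights,
high-degree hub alters are heavily down-weighted by their Laplacian degree
in the full network — the dilution that the egocentric extraction removes.
Both weightings remain selectable on every scoring function.

### Normalization and quartiles

Min-max normalization is applied over *all* nodes of the solved graph, ego
included (the normalization is written on $f$ without exclusions);
quartile groups are computed over alters only, ranked by normalized score
descending with ties broken by PheCode, the first three groups taking
⌈n/4⌉ members each. If the score vector is constant the normalized scores
are defined as all zeros, with a warning.

## The synthetic cohort

Real biobank inputs (individual-level EHR and genotypes) cannot be shared,
so the package ships a generator that reproduces the one structural
assumption the method rests on: *diseases sharing more causal variants
co-occur more often*.

The generative model is deliberately minimal and auditable:

* one synthetic chromosome, SNPs evenly spaced 50 kb apart, MAF drawn
  Uniform; genotypes Binomial(2, MAF) under Hardy-Weinberg, with no LD
  unless block-LD mode is switched on (adjacent SNPs copy their
  predecessor with probability $\sqrt{R^2_{target}}$ — used only to
  exercise the pruner);
* each disease has a fixed-size causal SNP set; *pleiotropy blocks* force
  exact shared-causal counts between member diseases;
* liability = effect\_size × sum of standardized causal dosages + N(0,1);
  a person is a case iff liability exceeds the (1 − prevalence) quantile
  of the theoretical liability distribution, whose SD is
  $\sqrt{m\beta^2 + 1}$ for $m$ causal SNPs of effect $\beta$ — so
  realized prevalence matches the target in expectation;
* diagnosis records thin true cases by a sensitivity and add false
  positives at rate 1 − specificity;
* the association scan is a per-(disease, SNP) allele-count chi-squared
  test (the cohort is unrelated and homogeneous, so no mixed-model
  relatedness correction is needed; the pipeline consumes only p-values,
  so any calibrated test suffices).

### The reference world and why its knobs sit where they do

`reference_config()` fixes the desk-scale world used throughout the
analysis scripts and the acceptance suite: 5,000 individuals, 500 SNPs,
15 diseases, effect size 0.5, ego-alter causal overlaps in {0, 5, 10}.
The free parameters were chosen once, before the acceptance measurements,
on two grounds:

* **EHR realism.** Diagnosis sensitivity 0.65 and specificity 0.98 are in
  the range routinely reported for EHR phenotyping of chronic disease;
  prevalence 0.10 and MAF Uniform(0.02, 0.2) are typical of the common
  diseases and low-frequency common variants that dominate PheWAS signal.
* **Informative labels.** With these values the 10-SNP-overlap pairs give
  phi-correlations comfortably past the significance cut while the
  5-SNP-overlap pairs sit near the detection limit, so comorbidity labels
  vary across alters and seeds — as they do in real data, where genetic
  sharing does not guarantee an observed comorbidity. A world with
  near-perfect diagnosis capture makes every connected pair significantly
  comorbid, every label positive, and AUC undefined.

The topology plants three ego-diseases, each with one strong alter
(overlap 10) and two weak alters (overlap 5); the strong alters are hubs,
each also sharing 10 causal SNPs with two background diseases. Hub alters
are the realistic stress case for the full-network baseline — exactly the
phenotypes (hypertension-like, diabetes-like) that are most connected in
real diseasomes.

### What the generator does *not* emulate

No realistic LD maps, population structure, relatedness, imputation error,
sex chromosomes, per-disease prevalence differences, or temporal structure
in the diagnosis records. A green test therefore establishes that the
*method* behaves as specified on data satisfying its core assumption — not
that the pipeline would achieve any particular accuracy on a real biobank.

## Numerical choices

* The propagation system $(I + \mu L)f = y$ is symmetric positive
  definite and solved by sparse Cholesky factorization; explicit inversion
  is never used. On a disconnected graph the system decouples, so
  components without the labelled node come out exactly zero and the
  labelled component's scores sum to 1.
* Phi significance uses the identity $\chi^2 = N\Phi^2$ on 1 df — the
  standard link between the phi coefficient and the 2 × 2 Pearson
  chi-squared, with no continuity correction (Fisher's exact test is
  available behind a flag for small counts). Degenerate margins give
  $\Phi = 0$, p = 1, flagged.
* AUC uses mid-ranks, so tied scores count 1/2 and an all-tied vector
  scores 0.5. Spearman p-values use the t-approximation, with an exact
  permutation option for n ≤ 10.
* The 2 × 2 independence test is the closed form
  $N(ad - bc)^2 / (r_1 r_2 c_1 c_2)$, no continuity correction by default
  (Yates behind a flag); odds ratios apply the 0.5 Haldane correction when
  a cell is empty. Expected cell counts below 5 raise a warning.
* LD pruning is per-phenotype, greedy in ascending p-value order (ties by
  position): a SNP is kept iff its R² with every already-kept SNP in its
  window is ≤ the threshold. Keep-best-by-p preserves the strongest
  signal of each clump; a position-first order and a global (union) mode
  are available, since the published recipe does not fix either choice.
* "Specified to the hundredth's place" is a strict string test on the
  PheCode's decimal part (two or more digits, so "642.10" counts);
  PheCode strings are canonical and never zero-padded, making the string
  test deterministic.
* Floats serialize at 6 significant digits (scientific below 1e-4), edge
  lists sort by (phecode\_a, phecode\_b), and shared SNP ids are stored
  sorted and semicolon-joined, so all artifacts are byte-stable under
  reruns; the one global seed expands into per-stage sub-seeds by hashing
  the stage name.
* One correction to a tempting intuition, encoded in the property tests:
  adding persons with *neither* disease to the cohort does not shrink a
  positive phi toward 0 — it moves phi monotonically toward its large-N
  limit $C_{ij}/\sqrt{P_i P_j}$, because co-absence agreement grows.

## Limitations

* Carrier status is "dosage ≥ 1 at ≥ 1 shared SNP"; risk-allele
  orientation is not modelled, since effect directions for the shared
  SNPs are not part of the network annotation.
* The full-network evaluation is restricted to each ego's alter set so
  both conditions score the same instances; truth is defined for alters
  only, so scoring all non-ego nodes would be ill-posed.
* Egos whose labels are all positive or all negative have undefined AUC
  and are dropped from averages (with a logged list) — with three alters
  per reference ego this happens in a minority of seeds.
* The same diagnosis records generate both the comorbidity labels and
  (indirectly, through the planted model) the network, mirroring the
  circularity inherent in any single-biobank design; the simulator cannot
  assess external validity.
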