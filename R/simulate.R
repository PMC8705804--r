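# Synthetic pleiotropic cohort generator. Individual-level biobank data
# cannot be shared, so the pipeline is exercised on a simulated cohort
# built to reproduce the one structural assumption the scoring method
# rests on: the more causal variants two diseases share, the more they
# co-occur.
#
# Generative model:
#   * per SNP, MAF ~ Uniform(maf_low, maf_high); dosages ~ Binomial(2, maf)
#     under Hardy-Weinberg (one synthetic chromosome, evenly spaced, no LD
#     unless block-LD mode is enabled);
#   * per disease, a causal SNP set of fixed size; pleiotropy blocks force
#     configured numbers of shared causal SNPs between member diseases,
#     all other causal SNPs are disease-private;
#   * liability = sum over causal SNPs of effect_size * standardized
#     dosage + N(0,1) noise; disease status = liability above the
#     (1 - prevalence) quantile of the theoretical liability distribution,
#     whose SD is sqrt(causal_per_disease * effect_size^2 + 1) — realized
#     prevalence matches the target in expectation;
#   * diagnosis records thin cases by diagnosis_sensitivity and add false
#     positives at rate (1 - diagnosis_specificity).

#' Simulation configuration
#'
#' @param n_individuals cohort size (>= 2)
#' @param n_snps number of variants on the single synthetic chromosome
#' @param n_diseases number of binary phenotypes
#' @param maf_low,maf_high Uniform MAF range
#' @param causal_per_disease causal SNPs per disease (<= n_snps)
#' @param pleiotropy_blocks list of `list(diseases = <1-based indices>,
#'   n_shared = <int>)`; diseases in a block share exactly `n_shared`
#'   causal SNPs (shared sets of distinct blocks are disjoint)
#' @param effect_size liability-scale effect per standardized allele
#' @param prevalence per-disease prevalence in (0, 1)
#' @param diagnosis_sensitivity probability a true case is recorded
#' @param diagnosis_specificity probability a non-case is *not* recorded
#' @param seed integer RNG seed; the cohort is a pure function of the config
#' @param spacing_bp base-pair spacing of consecutive SNPs
#' @param ld_block_size if > 1, consecutive SNPs form LD blocks of this
#'   size (only to exercise LD pruning; off by default)
#' @param ld_target_r2 target dosage R^2 between adjacent SNPs in a block
#' @return a `sim_config` list
#' @export
simulation_config <- function(n_individuals, n_snps, n_diseases,
                              maf_low = 0.05, maf_high = 0.5,
                              causal_per_disease = 20L,
                              pleiotropy_blocks = list(),
                              effect_size = 0.5, prevalence = 0.2,
                              diagnosis_sensitivity = 0.95,
                              diagnosis_specificity = 0.995,
                              seed = 1L, spacing_bp = 50000L,
                              ld_block_size = 1L, ld_target_r2 = 0.8) {
  stopifnot(n_individuals >= 2, n_snps >= 1, n_diseases >= 1,
            maf_low > 0, maf_high <= 0.5, maf_low <= maf_high,
            causal_per_disease >= 1, causal_per_disease <= n_snps,
            prevalence > 0, prevalence < 1,
            diagnosis_sensitivity >= 0, diagnosis_sensitivity <= 1,
            diagnosis_specificity > 0, diagnosis_specificity <= 1,
            ld_block_size >= 1, ld_target_r2 >= 0, ld_target_r2 <= 1)
  for (b in pleiotropy_blocks) {
    stopifnot(is.list(b), length(b$diseases) >= 2,
              all(b$diseases >= 1), all(b$diseases <= n_diseases),
              b$n_shared >= 0, b$n_shared <= causal_per_disease)
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_snps = as.integer(n_snps),
                 n_diseases = as.integer(n_diseases),
                 maf_low = maf_low, maf_high = maf_high,
                 causal_per_disease = as.integer(causal_per_disease),
                 pleiotropy_blocks = pleiotropy_blocks,
                 effect_size = effect_size, prevalence = prevalence,
                 diagnosis_sensitivity = diagnosis_sensitivity,
                 diagnosis_specificity = diagnosis_specificity,
                 seed = as.integer(seed), spacing_bp = as.integer(spacing_bp),
                 ld_block_size = as.integer(ld_block_size),
                 ld_target_r2 = ld_target_r2),
            class = "sim_config")
}

.disease_codes <- function(n) as.character(100L + seq_len(n))

.snp_codes <- function(n) sprintf("rs%05d", seq_len(n))

# Assign causal SNP sets: block-shared SNPs first (disjoint across blocks),
# then disease-private fill, all from a shuffled pool so sets are random
# but exact in size and overlap.
.assign_causal_sets <- function(cfg) {
  pool <- sample.int(cfg$n_snps)              # shuffled SNP indices
  take <- function(k) {
    if (k == 0L) return(integer())     # pool[-integer(0)] would drop everything
    if (k > length(pool)) stop("n_snps too small for the configured causal sets",
                               call. = FALSE)
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  sets <- rep(list(integer()), cfg$n_diseases)
  for (b in cfg$pleiotropy_blocks) {
    sh <- take(b$n_shared)
    for (d in b$diseases) sets[[d]] <- c(sets[[d]], sh)
  }
  for (d in seq_len(cfg$n_diseases)) {
    if (length(sets[[d]]) > cfg$causal_per_disease)
      stop("disease ", d, " accumulates more block-shared SNPs than ",
           "causal_per_disease", call. = FALSE)
    sets[[d]] <- sort(c(sets[[d]], take(cfg$causal_per_disease - length(sets[[d]]))))
  }
  sets
}

.draw_genotypes <- function(cfg, maf) {
  n <- cfg$n_individuals; m <- cfg$n_snps
  if (cfg$ld_block_size <= 1L) {
    return(matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m))
  }
  # Block-LD mode: within a block of consecutive SNPs (sharing the block
  # head's MAF), each SNP copies its predecessor's genotype per person with
  # probability q = sqrt(target R^2), else draws fresh; dosage correlation
  # between neighbours is then q, i.e. R^2 ~ target.
  q <- sqrt(cfg$ld_target_r2)
  G <- matrix(0L, n, m)
  block <- (seq_len(m) - 1L) %/% cfg$ld_block_size
  for (j in seq_len(m)) {
    head_of_block <- j == 1L || block[j] != block[j - 1L]
    p <- maf[min(which(block == block[j]))]
    fresh <- stats::rbinom(n, 2L, p)
    if (head_of_block) {
      G[, j] <- fresh
    } else {
      copy <- stats::runif(n) < q
      G[, j] <- ifelse(copy, G[, j - 1L], fresh)
    }
  }
  G
}

#' Simulate a pleiotropic cohort
#'
#' Draws genotypes, assigns causal SNP sets honouring the configured
#' pleiotropy blocks, and generates liability-threshold disease statuses.
#' Deterministic given the config (which includes the seed).
#'
#' @param config a [simulation_config()]
#' @return a `synthetic_cohort`: list with `genotypes`
#'   (a `genotype_matrix`), `disease_status` (person x disease 0/1 matrix,
#'   columns named by phecode), `causal_sets` (named list of SNP-id
#'   vectors, the ground-truth per-disease sets), `maf` (true simulated
#'   MAFs), `phenotype_info`, and `config`
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  maf <- stats::runif(config$n_snps, config$maf_low, config$maf_high)
  causal_idx <- .assign_causal_sets(config)
  G <- .draw_genotypes(config, maf)
  person_ids <- sprintf("P%06d", seq_len(config$n_individuals))
  snp_ids <- .snp_codes(config$n_snps)
  phecodes <- .disease_codes(config$n_diseases)

  # standardize dosages with the *true* MAF (HWE variance 2p(1-p))
  liab_sd <- sqrt(config$causal_per_disease * config$effect_size^2 + 1)
  thresh <- stats::qnorm(1 - config$prevalence, sd = liab_sd)
  status <- matrix(0L, config$n_individuals, config$n_diseases,
                   dimnames = list(person_ids, phecodes))
  for (d in seq_len(config$n_diseases)) {
    idx <- causal_idx[[d]]
    Z <- sweep(G[, idx, drop = FALSE], 2L, 2 * maf[idx], "-")
    Z <- sweep(Z, 2L, sqrt(2 * maf[idx] * (1 - maf[idx])), "/")
    liability <- rowSums(Z) * config$effect_size +
      stats::rnorm(config$n_individuals)
    status[, d] <- as.integer(liability > thresh)
  }

  categories <- c("circulatory system", "endocrine/metabolic",
                  "genitourinary", "pregnancy complications", "digestive")
  info <- data.frame(
    phecode = phecodes,
    name = paste("synthetic disease", phecodes),
    category = categories[(seq_len(config$n_diseases) - 1L) %%
                            length(categories) + 1L],
    sex_specific = "none", stringsAsFactors = FALSE)

  structure(list(
    genotypes = genotype_matrix(G, person_ids, snp_ids),
    disease_status = status,
    causal_sets = stats::setNames(lapply(causal_idx, function(i) snp_ids[i]),
                                  phecodes),
    maf = stats::setNames(maf, snp_ids),
    phenotype_info = info,
    config = config), class = "synthetic_cohort")
}

# 2x2 allele-count chi-squared, vectorized over SNPs. a/b = alt/ref allele
# counts in cases, c/d in controls. Zero-margin tables get stat 0, p 1.
.allele_chisq <- function(alt_case, n_case, alt_ctrl, n_ctrl) {
  a <- alt_case; b <- 2 * n_case - a
  c_ <- alt_ctrl; d <- 2 * n_ctrl - c_
  N <- a + b + c_ + d
  m1 <- a + b; m2 <- c_ + d; m3 <- a + c_; m4 <- b + d
  stat <- numeric(length(a))
  ok <- m1 > 0 & m2 > 0 & m3 > 0 & m4 > 0
  stat[ok] <- N[ok] * (a[ok] * d[ok] - b[ok] * c_[ok])^2 /
    (m1[ok] * m2[ok] * m3[ok] * m4[ok])
  p <- rep(1, length(a))
  p[ok] <- stats::pchisq(stat[ok], df = 1, lower.tail = FALSE)
  list(stat = stat, pvalue = p)
}

#' Case-control association scan of a synthetic cohort
#'
#' For every (disease, SNP) pair, tests the 2x2 allele-count table
#' (alternate/reference allele x case/control) with a Pearson chi-squared
#' statistic on 1 df; the p-value is the upper-tail probability. MAF is
#' computed from the full cohort and folded to the minor allele; SNPs that
#' are monomorphic in the cohort carry no signal and are dropped with a
#' warning. Diseases with zero cases or zero controls are skipped with a
#' warning. Positions place the SNPs evenly on one synthetic chromosome.
#'
#' @param cohort a `synthetic_cohort`
#' @return summary-stat data.frame in the [read_summary_stats()] schema
#' @export
association_scan <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  G <- cohort$genotypes$dosages
  snp_ids <- cohort$genotypes$snp_ids
  n <- nrow(G)
  freq <- colMeans(G) / 2
  maf <- pmin(freq, 1 - freq)
  poly <- maf > 0
  if (any(!poly))
    warning(sum(!poly), " monomorphic SNP(s) dropped from the scan")
  alt_total <- colSums(G)
  pos <- cohort$config$spacing_bp * seq_along(snp_ids)
  out <- list()
  for (code in colnames(cohort$disease_status)) {
    cases <- cohort$disease_status[, code] == 1L
    n_case <- sum(cases); n_ctrl <- n - n_case
    if (n_case == 0L || n_ctrl == 0L) {
      warning("disease ", code, " has no cases or no controls; skipped")
      next
    }
    alt_case <- colSums(G[cases, , drop = FALSE])
    tst <- .allele_chisq(alt_case, n_case, alt_total - alt_case, n_ctrl)
    out[[code]] <- data.frame(
      phecode = code, snp_id = snp_ids[poly], chrom = "1",
      pos = as.integer(pos[poly]),
      pvalue = pmax(tst$pvalue[poly], .Machine$double.xmin),
      maf = maf[poly], n_cases = n_case,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Emit diagnosis records from simulated disease status
#'
#' Each true case is recorded as a PheCode diagnosis with probability
#' `diagnosis_sensitivity`; each non-case with probability
#' `1 - diagnosis_specificity`. Deterministic given the seed.
#'
#' @param cohort a `synthetic_cohort`
#' @param seed RNG seed (defaults to the cohort seed + 1, so diagnosis
#'   noise is independent of the genotype draw)
#' @return diagnosis data.frame in the [read_diagnoses()] schema
#' @export
emit_diagnoses <- function(cohort, seed = cohort$config$seed + 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  set.seed(seed)
  st <- cohort$disease_status
  sens <- cohort$config$diagnosis_sensitivity
  fpr <- 1 - cohort$config$diagnosis_specificity
  p_emit <- ifelse(st == 1L, sens, fpr)
  emitted <- matrix(stats::runif(length(st)) < p_emit, nrow(st), ncol(st))
  idx <- which(emitted, arr.ind = TRUE)
  out <- data.frame(person_id = rownames(st)[idx[, 1L]],
                    code = colnames(st)[idx[, 2L]],
                    code_system = rep("PheCode", nrow(idx)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$person_id, out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write ground-truth causal SNP sets
#' @param cohort a `synthetic_cohort`
#' @param path output `.tsv` path (columns `phecode`, `snp_id`)
#' @export
write_causal_sets <- function(cohort, path) {
  df <- data.frame(
    phecode = rep(names(cohort$causal_sets),
                  lengths(cohort$causal_sets)),
    snp_id = unlist(cohort$causal_sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  .write_table(df, path)
}
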