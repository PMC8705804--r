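# The generator's planted structure: shared causal SNPs must show up both
# as shared significant associations and as elevated co-occurrence.

test_that("cohort simulation is a pure function of the config", {
  cfg <- simulation_config(200, 50, 3, causal_per_disease = 5L, seed = 11L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$disease_status, b$disease_status)
  expect_identical(a$causal_sets, b$causal_sets)
  expect_identical(emit_diagnoses(a), emit_diagnoses(b))
  expect_identical(association_scan(a), association_scan(b))
})

test_that("pleiotropy blocks plant exact causal overlaps", {
  cfg <- simulation_config(50, 200, 4, causal_per_disease = 20L,
                           pleiotropy_blocks = list(
                             list(diseases = c(1L, 2L), n_shared = 7L),
                             list(diseases = c(2L, 3L), n_shared = 5L)),
                           seed = 3L)
  co <- simulate_cohort(cfg)
  cs <- co$causal_sets
  expect_true(all(lengths(cs) == 20L))
  expect_length(intersect(cs[["101"]], cs[["102"]]), 7L)
  expect_length(intersect(cs[["102"]], cs[["103"]]), 5L)
  expect_length(intersect(cs[["101"]], cs[["103"]]), 0L)
  expect_length(intersect(cs[["101"]], cs[["104"]]), 0L)

  bad <- simulation_config(50, 30, 4, causal_per_disease = 20L,
                           pleiotropy_blocks = list(
                             list(diseases = c(1L, 2L), n_shared = 7L)),
                           seed = 3L)
  expect_error(simulate_cohort(bad), "n_snps too small")
  expect_error(simulation_config(50, 30, 2, pleiotropy_blocks = list(
    list(diseases = c(1L, 5L), n_shared = 2L))))
})

test_that("no genetic sharing means independent diseases", {
  # effect 0 cuts every genotype-phenotype link; phi centers on 0
  phis <- vapply(1:25, function(s) {
    cfg <- simulation_config(2000, 10, 2, causal_per_disease = 5L,
                             effect_size = 0, prevalence = 0.2, seed = s)
    co <- simulate_cohort(cfg)
    oracle_phi_pearson(co$disease_status[, 1], co$disease_status[, 2])
  }, numeric(1))
  expect_lt(abs(mean(phis)), 0.02)
})

test_that("full causal sharing produces significant co-occurrence", {
  hits <- vapply(1:10, function(s) {
    cfg <- simulation_config(5000, 40, 2, causal_per_disease = 20L,
                             pleiotropy_blocks = list(
                               list(diseases = c(1L, 2L), n_shared = 20L)),
                             effect_size = 0.5, prevalence = 0.2, seed = s)
    co <- simulate_cohort(cfg)
    ids <- co$genotypes$person_ids
    dg <- data.frame(person_id = rep(ids, 2),
                     code = rep(c("101", "102"), each = length(ids)),
                     code_system = "PheCode")[c(co$disease_status) == 1L, ]
    st <- phi_correlation(dg, c("101", "102"), ids)
    st$phi > 0 && st$pvalue < 0.05
  }, logical(1))
  expect_true(all(hits))
})

test_that("planted overlap translates monotonically into co-occurrence", {
  # same ego paired at overlaps 0 / 5 / 10: mean phi strictly increasing
  mean_phi <- sapply(c(0L, 5L, 10L), function(k) {
    mean(vapply(1:10, function(s) {
      blocks <- if (k > 0L) list(list(diseases = c(1L, 2L), n_shared = k))
                else list()
      cfg <- simulation_config(5000, 60, 2, causal_per_disease = 20L,
                               pleiotropy_blocks = blocks, effect_size = 0.5,
                               prevalence = 0.2, seed = 100L + s)
      co <- simulate_cohort(cfg)
      oracle_phi_pearson(co$disease_status[, 1], co$disease_status[, 2])
    }, numeric(1)))
  })
  expect_true(mean_phi[1] < mean_phi[2] && mean_phi[2] < mean_phi[3])
})

test_that("allele-count chi-squared matches the contingency oracle", {
  # constructed table [[120, 80], [80, 120]] (alt/ref x case/control)
  res <- egoddn:::.allele_chisq(alt_case = 120, n_case = 100,
                                alt_ctrl = 80, n_ctrl = 100)
  expect_equal(res$stat, 16.0, tolerance = 1e-12)
  expect_equal(res$pvalue, 6.334248e-05, tolerance = 1e-6)
  expect_equal(res$stat,
               oracle_chi2_expected(matrix(c(120, 80, 80, 120), 2)),
               tolerance = 1e-10)

  # equal allele frequencies in cases and controls: no signal
  flat <- egoddn:::.allele_chisq(50, 50, 50, 50)
  expect_equal(flat$stat, 0)
  expect_equal(flat$pvalue, 1)

  # zero allele-count margin (monomorphic): pvalue 1 by convention
  mono <- egoddn:::.allele_chisq(0, 50, 0, 50)
  expect_equal(mono$pvalue, 1)
})

test_that("association scan detects planted causal SNPs", {
  hits <- vapply(1:15, function(s) {
    cfg <- simulation_config(4000, 30, 1, causal_per_disease = 10L,
                             effect_size = 0.8, prevalence = 0.3,
                             maf_low = 0.1, maf_high = 0.4, seed = s)
    co <- simulate_cohort(cfg)
    ss <- association_scan(co)
    causal <- co$causal_sets[["101"]]
    mean(ss$pvalue[ss$snp_id %in% causal] <= 1e-4)
  }, numeric(1))
  expect_gte(mean(hits >= 0.9), 0.9)
})

test_that("scan p-values are calibrated under the null", {
  # non-causal SNPs across many diseases: ~5% at p <= 0.05
  cfg <- simulation_config(5000, 500, 22, causal_per_disease = 10L,
                           effect_size = 0.5, prevalence = 0.2, seed = 9L)
  co <- simulate_cohort(cfg)
  ss <- association_scan(co)
  null_rows <- !mapply(function(p, s) s %in% co$causal_sets[[p]],
                       ss$phecode, ss$snp_id)
  expect_gt(sum(null_rows), 10000)
  frac <- mean(ss$pvalue[null_rows] <= 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("scan skips case-free diseases and fills schema fields", {
  cfg <- simulation_config(300, 20, 2, causal_per_disease = 5L,
                           prevalence = 0.2, seed = 5L)
  co <- simulate_cohort(cfg)
  co$disease_status[, 2] <- 0L
  expect_warning(ss <- association_scan(co), "no cases")
  expect_setequal(unique(ss$phecode), "101")
  expect_equal(ss$n_cases, rep(sum(co$disease_status[, 1]), nrow(ss)))
  expect_true(all(diff(ss$pos) == co$config$spacing_bp))
  expect_true(all(ss$maf > 0 & ss$maf <= 0.5))
})

test_that("diagnosis emission respects sensitivity and specificity", {
  cfg <- simulation_config(2000, 10, 2, causal_per_disease = 3L,
                           prevalence = 0.3,
                           diagnosis_sensitivity = 1, diagnosis_specificity = 1,
                           seed = 21L)
  co <- simulate_cohort(cfg)
  dg <- emit_diagnoses(co)
  truth <- which(co$disease_status == 1L, arr.ind = TRUE)
  expect_equal(nrow(dg), nrow(truth))
  expect_setequal(paste(dg$person_id, dg$code),
                  paste(rownames(co$disease_status)[truth[, 1]],
                        colnames(co$disease_status)[truth[, 2]]))

  cfg0 <- simulation_config(500, 10, 1, causal_per_disease = 3L,
                            prevalence = 0.3, diagnosis_sensitivity = 0,
                            diagnosis_specificity = 1, seed = 21L)
  expect_equal(nrow(emit_diagnoses(simulate_cohort(cfg0))), 0L)

  # thinning at sensitivity 0.8: emitted count inside the binomial 99% band
  cfg8 <- simulation_config(4000, 10, 1, causal_per_disease = 3L,
                            prevalence = 0.25, diagnosis_sensitivity = 0.8,
                            diagnosis_specificity = 1, seed = 22L)
  co8 <- simulate_cohort(cfg8)
  n_cases <- sum(co8$disease_status)
  emitted <- nrow(emit_diagnoses(co8))
  band <- stats::qbinom(c(0.005, 0.995), n_cases, 0.8)
  expect_gte(emitted, band[1])
  expect_lte(emitted, band[2])
})
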