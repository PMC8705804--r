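test_that("association filters keep exactly the boundary-inclusive survivors", {
  fx <- boundary_fixture()
  kept <- suppressMessages(
    filter_associations(fx$records, fx$phenos, filter_config()))
  expect_equal(kept, fx$records[fx$survivors, ], ignore_attr = TRUE)

  # p = 1e-4, MAF = 0.01, cases = 200 are all inclusive boundaries
  expect_true("rs1" %in% kept$snp_id[kept$phecode == "642"])
  expect_true(any(kept$maf == 0.01))
  expect_true(any(kept$n_cases == 200L))
  # hundredth's-place PheCode and male-specific phenotype dropped entirely
  expect_false(any(kept$phecode %in% c("642.11", "185")))
})

test_that("hundredth's-place PheCode rule is a strict string test", {
  expect_equal(egoddn:::is_hundredths_phecode(
    c("642", "642.1", "642.11", "642.10", "1010.23", "8")),
    c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("unknown phecode in records is an error naming the code", {
  fx <- boundary_fixture()
  expect_error(
    filter_associations(fx$records, fx$phenos[-1, ], filter_config()),
    "642")
})

test_that("numeric filters commute and p_max loosening is monotone", {
  set.seed(41)
  recs <- make_summary_df(sample(c("100", "200", "300"), 60, TRUE),
                          paste0("rs", 1:60),
                          pvalue = 10^stats::runif(60, -8, 0),
                          maf = stats::runif(60, 0.001, 0.5),
                          n_cases = sample(50:1000, 60, TRUE))
  phenos <- make_pheno_df(c("100", "200", "300"))
  cfg <- filter_config()
  joint <- suppressMessages(filter_associations(recs, phenos, cfg))

  one_at_a_time <- recs
  for (cf in list(filter_config(maf_min = 0, min_cases = 0L),
                  filter_config(p_max = 1, min_cases = 0L),
                  filter_config(p_max = 1, maf_min = 0))) {
    one_at_a_time <- suppressMessages(
      filter_associations(one_at_a_time, phenos, cf))
  }
  expect_equal(joint, one_at_a_time, ignore_attr = TRUE)

  loose <- suppressMessages(
    filter_associations(recs, phenos, filter_config(p_max = 1e-2)))
  expect_true(all(paste(joint$phecode, joint$snp_id) %in%
                    paste(loose$phecode, loose$snp_id)))
})

test_that("LD pruning keeps the best-p SNP of each correlated pair in window", {
  # rsA/rsB 100 kb apart, strongly correlated dosages; rsC far away but
  # correlated with rsA; rsD nearby but orthogonal
  x <- rep(c(0L, 1L, 2L), each = 10)
  y <- x; y[c(1, 2, 11, 12)] <- c(1L, 1L, 0L, 2L)   # cor^2 with x > 0.2
  z <- rep(c(0L, 1L, 2L), times = 10)               # orthogonal to x
  expect_gt(stats::cor(x, y)^2, 0.2)
  expect_lt(stats::cor(x, z)^2, 0.2)
  gm <- genotype_matrix(cbind(x, y, x, z),
                        sprintf("p%02d", 1:30), c("rsA", "rsB", "rsC", "rsD"))
  recs <- make_summary_df("100", c("rsA", "rsB", "rsC", "rsD"),
                          pvalue = c(1e-8, 1e-5, 1e-6, 1e-7),
                          pos = c(100000L, 200000L, 500000L, 210000L))
  kept <- suppressMessages(ld_prune(recs, gm, filter_config()))
  # rsB pruned by rsA (in window, high R2, worse p); rsC kept despite
  # R2 = 1 with rsA because 400 kb > 250 kb window; rsD orthogonal, kept
  expect_setequal(kept$snp_id, c("rsA", "rsC", "rsD"))
})

test_that("orthogonal dosages survive pruning untouched", {
  set.seed(7)
  G <- matrix(rep(c(0L, 1L, 2L), times = 4), ncol = 4)   # identical columns
  G <- cbind(rep(c(0L, 1L, 2L), each = 4)[1:12],
             rep(c(2L, 1L, 0L, 1L), times = 3),
             rep(c(0L, 2L), times = 6))
  gm <- genotype_matrix(G, sprintf("p%02d", 1:12), c("rs1", "rs2", "rs3"))
  r2 <- stats::cor(G)^2
  expect_true(all(r2[upper.tri(r2)] <= 0.2))
  recs <- make_summary_df("100", c("rs1", "rs2", "rs3"),
                          pvalue = c(1e-5, 1e-6, 1e-7),
                          pos = c(1000L, 2000L, 3000L))
  kept <- suppressMessages(ld_prune(recs, gm, filter_config()))
  expect_equal(nrow(kept), 3L)
})

test_that("pruning output is maximal under the greedy rule", {
  set.seed(13)
  cfg <- simulation_config(400, 60, 2, causal_per_disease = 10L,
                           ld_block_size = 4L, ld_target_r2 = 0.6, seed = 13L)
  co <- simulate_cohort(cfg)
  ss <- suppressWarnings(association_scan(co))
  ss <- ss[ss$phecode == "101", ]
  kept <- suppressMessages(ld_prune(ss, co$genotypes, filter_config()))
  removed <- setdiff(ss$snp_id, kept$snp_id)
  expect_gt(length(removed), 0L)         # block-LD mode must trigger pruning
  window <- 250000
  for (snp in removed) {
    pos_r <- ss$pos[ss$snp_id == snp]
    near <- kept$snp_id[abs(kept$pos - pos_r) <= window]
    r2 <- stats::cor(co$genotypes$dosages[, snp],
                     co$genotypes$dosages[, near, drop = FALSE])^2
    expect_gt(max(r2), 0.2)
  }
})

test_that("missing genotype SNP is an error naming the SNP", {
  gm <- genotype_matrix(matrix(rep(c(0L, 1L, 2L), 2), ncol = 2),
                        c("p1", "p2", "p3"), c("rs1", "rs2"))
  recs <- make_summary_df("100", c("rs1", "rsX"), pvalue = c(1e-5, 1e-5))
  expect_error(ld_prune(recs, gm, filter_config()), "rsX")
})

test_that("association matrix conserves counts and deduplicates", {
  recs <- make_summary_df(c("A", "A", "B", "B"), c("s1", "s2", "s2", "s3"),
                          pvalue = 1e-5)
  m <- build_matrix(recs)
  expect_equal(sum(m$assoc), 4L)
  expect_equal(dim(m$assoc), c(2L, 3L))

  dup <- rbind(recs, recs[1, ])
  expect_equal(sum(build_matrix(dup)$assoc), 4L)

  expect_error(build_matrix(recs[0, ]), "no associations survive")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path)
  expect_equal(read_matrix(path)$assoc, m$assoc)
})

test_that("filtering recovers planted causal sets with high recall", {
  recalls <- vapply(1:5, function(s) {
    cfg <- simulation_config(5000, 300, 5, causal_per_disease = 20L,
                             effect_size = 0.8, prevalence = 0.2,
                             maf_low = 0.05, maf_high = 0.5, seed = 200L + s)
    co <- simulate_cohort(cfg)
    ss <- suppressWarnings(association_scan(co))
    kept <- suppressMessages(
      filter_associations(ss, co$phenotype_info, filter_config()))
    kept <- suppressMessages(ld_prune(kept, co$genotypes, filter_config()))
    mean(vapply(names(co$causal_sets), function(ph) {
      found <- kept$snp_id[kept$phecode == ph]
      mean(co$causal_sets[[ph]] %in% found)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(recalls >= 0.8))
})
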