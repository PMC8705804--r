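test_that("ICD records expand to all mapped PheCodes and deduplicate", {
  map <- data.frame(icd_code = c("I10", "I10", "401.0"),
                    icd_version = c(10L, 10L, 9L),
                    phecode = c("401", "401.1", "401"),
                    stringsAsFactors = FALSE)
  recs <- data.frame(person_id = c("p1", "p1", "p2"),
                     code = c("I10", "401.0", "XXX"),
                     code_system = c("ICD10", "ICD9", "ICD10"),
                     stringsAsFactors = FALSE)
  expect_warning(out <- map_diagnoses_to_phecodes(recs, map),
                 "1 diagnosis record")
  # p1 reaches 401 via both ICD10 and ICD9: one record after dedup
  expect_equal(out[out$person_id == "p1", "code"], c("401", "401.1"))
  expect_false("p2" %in% out$person_id)
  expect_true(all(out$code_system == "PheCode"))

  # PheCode records pass through untouched
  phe <- data.frame(person_id = "p3", code = "642.1", code_system = "PheCode",
                    stringsAsFactors = FALSE)
  expect_equal(map_diagnoses_to_phecodes(phe, map)$code, "642.1")
})

make_diag <- function(ids_i, ids_j, code_i = "A", code_j = "B") {
  data.frame(person_id = c(ids_i, ids_j),
             code = c(rep(code_i, length(ids_i)), rep(code_j, length(ids_j))),
             code_system = "PheCode", stringsAsFactors = FALSE)
}

test_that("phi-correlation reproduces worked 2x2 configurations", {
  ids <- sprintf("p%03d", 1:100)
  # N=100, P_i=20, P_j=30, C=6: exact independence (6*100 = 20*30)
  dg <- make_diag(ids[1:20], ids[c(1:6, 21:44)])
  st <- phi_correlation(dg, c("A", "B"), ids)
  expect_equal(st$phi, 0, tolerance = 1e-15)
  expect_equal(st$C_ij, 6L)

  # N=100, P_i=P_j=C=10: perfect co-occurrence
  st1 <- phi_correlation(make_diag(ids[1:10], ids[1:10]), c("A", "B"), ids)
  expect_equal(st1$phi, 1, tolerance = 1e-12)

  # N=200, P_i=50, P_j=40, C=20 -> phi = 2000/sqrt(4.8e7), chi2 ~ 16.667
  ids2 <- sprintf("p%03d", 1:200)
  dg2 <- make_diag(ids2[1:50], ids2[c(1:20, 51:70)])
  st2 <- phi_correlation(dg2, c("A", "B"), ids2)
  expect_equal(st2$phi, 2000 / sqrt(48e6), tolerance = 1e-12)
  expect_equal(st2$phi, 0.288675, tolerance = 1e-6)
  expect_equal(st2$pvalue, 4.455709e-05, tolerance = 1e-6)
  # chi2 = N phi^2 is algebraically the 2x2 Pearson statistic
  tab <- matrix(c(20, 30, 20, 130), 2)
  expect_equal(200 * st2$phi^2, oracle_chi2_expected(tab), tolerance = 1e-10)

  expect_error(phi_correlation(dg, c("A", "A"), ids), "self-pair")
})

test_that("phi equals the Pearson correlation of indicator vectors", {
  set.seed(61)
  for (rep in 1:200) {
    N <- sample(10:200, 1)
    ids <- sprintf("p%04d", seq_len(N))
    has_i <- stats::rbinom(N, 1, stats::runif(1, 0.05, 0.9))
    has_j <- stats::rbinom(N, 1, stats::runif(1, 0.05, 0.9))
    dg <- make_diag(ids[has_i == 1], ids[has_j == 1])
    st <- phi_correlation(dg, c("A", "B"), ids)
    oracle <- oracle_phi_pearson(has_i, has_j)
    if (st$degenerate) {
      expect_true(is.na(oracle) || all(has_i == has_j))
    } else {
      expect_equal(st$phi, oracle, tolerance = 1e-12)
      # symmetry and range
      expect_equal(phi_correlation(dg, c("B", "A"), ids)$phi, st$phi,
                   tolerance = 1e-15)
      expect_true(st$phi >= -1 && st$phi <= 1)
    }
  }
})

test_that("the comorbidity truth rule needs positive, significant, joint cases", {
  ids <- sprintf("p%03d", 1:200)
  pos <- phi_correlation(make_diag(ids[1:50], ids[c(1:20, 51:70)]),
                         c("A", "B"), ids)
  expect_true(pos$is_comorbid)      # phi > 0, p < 0.05, C > 0

  # strong *negative* association is never comorbidity
  neg <- phi_correlation(make_diag(ids[1:100], ids[101:200]), c("A", "B"), ids)
  expect_lt(neg$phi, 0)
  expect_lt(neg$pvalue, 0.05)
  expect_false(neg$is_comorbid)

  # disease absent from the cohort: degenerate, never comorbid
  degen <- phi_correlation(make_diag(ids[1:50], character(0)), c("A", "B"), ids)
  expect_true(degen$degenerate)
  expect_equal(degen$phi, 0)
  expect_equal(degen$pvalue, 1)
  expect_false(degen$is_comorbid)
})

test_that("diluting the cohort moves phi monotonically toward C/sqrt(PiPj)", {
  # adding neither-disease persons increases co-absence agreement, so a
  # positive phi climbs monotonically toward its large-N limit
  ids <- sprintf("p%03d", 1:60)
  dg <- make_diag(ids[1:20], ids[c(1:15, 21:25)])   # C=15, P_i=P_j=20
  limit <- 15 / sqrt(20 * 20)
  prev <- -Inf
  for (N in c(60, 120, 240, 480, 10000)) {
    universe <- sprintf("q%05d", seq_len(N))
    universe[1:60] <- ids
    st <- phi_correlation(dg, c("A", "B"), universe)
    expect_gt(st$phi, prev)
    expect_lte(st$phi, limit)
    prev <- st$phi
  }
  expect_equal(prev, limit, tolerance = 1e-2)
})

test_that("label_alters covers every alter including undiagnosed ones", {
  ddn <- build_full_ddn(matrix_from_supports(fig_supports()))
  net <- extract_ego_network(ddn, "d1")
  ids <- sprintf("p%03d", 1:100)
  dg <- rbind(make_diag(ids[1:30], ids[1:25], "d1", "d2"),
              make_diag(ids[5:20], character(0), "d3", "unused"))
  truth <- label_alters(net, dg, ids)
  expect_equal(truth$phecode_j, paste0("d", 2:6))
  expect_true(all(truth$phecode_i == "d1"))
  # d4..d6 never diagnosed: degenerate rows, not errors
  expect_true(all(truth$degenerate[truth$phecode_j %in% c("d4", "d5", "d6")]))
  expect_true(truth$is_comorbid[truth$phecode_j == "d2"])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(truth, path)
  expect_equal(nrow(utils::read.delim(path)), 5L)
})

test_that("Fisher's exact option changes only the p-value route", {
  ids <- sprintf("p%03d", 1:40)
  dg <- make_diag(ids[1:6], ids[c(1:3, 7:10)])
  chi <- phi_correlation(dg, c("A", "B"), ids)
  fis <- phi_correlation(dg, c("A", "B"), ids, fisher = TRUE)
  expect_equal(fis$phi, chi$phi)
  expect_equal(fis$pvalue,
               stats::fisher.test(matrix(c(3, 3, 4, 30), 2))$p.value,
               tolerance = 1e-12)
})
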