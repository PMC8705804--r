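# Individual-level stratification: among persons diagnosed with the
# ego-disease, does carrying at least one alternate allele at any of the
# SNPs shared between the ego and an alter associate with being diagnosed
# with both diseases? Tested with a Pearson chi-squared test for
# independence on the 2x2 table (carrier status x diagnosis group).

#' Build the carrier-by-comorbidity contingency table
#'
#' Population: persons ever diagnosed with the ego-disease. Columns split
#' by alter diagnosis (`both_diseases` vs `ego_only`); rows split by
#' carrier status — dosage >= 1 at at least one SNP of the shared set S.
#' Risk-allele orientation is not modeled: "carrier" means carrying any
#' alternate allele at any shared SNP.
#'
#' @param ego,alter phecodes of the disease pair
#' @param shared one-row edge data.frame ([edge_annotation()]) whose
#'   `shared_snp_ids` defines S
#' @param genotypes a `genotype_matrix` containing all SNPs of S
#' @param diagnoses PheCode diagnosis records
#' @return a `contingency_2x2`: 2x2 integer matrix with rows
#'   (carrier, non_carrier) and columns (both_diseases, ego_only)
#' @export
build_contingency <- function(ego, alter, shared, genotypes, diagnoses) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  snps <- shared_snps(shared)
  if (length(snps) < 1L) stop("empty shared SNP set", call. = FALSE)
  miss <- setdiff(snps, genotypes$snp_ids)
  if (length(miss) > 0L)
    stop("shared SNP(s) absent from genotypes: ",
         paste(miss, collapse = ", "), call. = FALSE)
  with_ego <- unique(diagnoses$person_id[diagnoses$code == ego])
  with_ego <- intersect(with_ego, genotypes$person_ids)
  if (length(with_ego) == 0L)
    stop("empty stratification population: nobody diagnosed with '", ego, "'",
         call. = FALSE)
  with_alter <- unique(diagnoses$person_id[diagnoses$code == alter])
  G <- genotypes$dosages[with_ego, snps, drop = FALSE]
  carrier <- rowSums(G >= 1L) > 0L
  both <- with_ego %in% with_alter
  tab <- matrix(c(sum(carrier & both), sum(!carrier & both),
                  sum(carrier & !both), sum(!carrier & !both)),
                nrow = 2L, byrow = FALSE,
                dimnames = list(c("carrier", "non_carrier"),
                                c("both_diseases", "ego_only")))
  structure(tab, class = c("contingency_2x2", "matrix"), snps = snps)
}

#' Chi-squared test of independence on a 2x2 table
#'
#' Pearson chi-squared on 1 df, no continuity correction by default
#' (Yates available behind `correct`). Uses the closed form
#' N (ad - bc)^2 / (r1 r2 c1 c2); a zero row or column margin yields a
#' degenerate result (chi2 = 0, p = 1). The odds ratio applies the 0.5
#' Haldane correction when any cell is zero. A warning is issued when any
#' expected cell count is below 5.
#'
#' @param table a 2x2 numeric matrix (e.g. from [build_contingency()])
#' @param correct apply Yates' continuity correction
#' @return a `stratification_result` list: `table`, `chi2`, `pvalue`,
#'   `odds_ratio`, `degenerate`, `shared_snp_ids`
#' @export
chi_squared_test <- function(table, correct = FALSE) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  a <- table[1L, 1L]; b <- table[1L, 2L]
  c_ <- table[2L, 1L]; d <- table[2L, 2L]
  N <- a + b + c_ + d
  if (N < 1L) stop("empty contingency table", call. = FALSE)
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) {
    chi2 <- 0; pv <- 1; degen <- TRUE
  } else {
    degen <- FALSE
    expected <- outer(c(a + b, c_ + d), c(a + c_, b + d)) / N
    if (any(expected < 5))
      warning("expected cell count below 5; chi-squared approximation may be poor")
    num <- abs(a * d - b * c_)
    if (correct) num <- max(0, num - N / 2)
    chi2 <- N * num^2 / prod(margins)
    pv <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  or_tab <- c(a, b, c_, d)
  if (any(or_tab == 0)) or_tab <- or_tab + 0.5      # Haldane correction
  or <- (or_tab[1L] * or_tab[4L]) / (or_tab[2L] * or_tab[3L])
  structure(list(table = table, chi2 = chi2, pvalue = pv, odds_ratio = or,
                 degenerate = degen,
                 shared_snp_ids = attr(table, "snps")),
            class = "stratification_result")
}

#' Carrier stratification for one connected disease pair
#'
#' Convenience wrapper: looks up the shared-SNP edge in the network,
#' builds the contingency table and runs the chi-squared test.
#'
#' @param ddn a `weighted_ddn` containing the ego-alter edge
#' @param ego,alter phecodes of the connected pair
#' @param genotypes a `genotype_matrix`
#' @param diagnoses PheCode diagnosis records
#' @param correct Yates' correction, passed to [chi_squared_test()]
#' @return a `stratification_result`
#' @export
stratify_pair <- function(ddn, ego, alter, genotypes, diagnoses,
                          correct = FALSE) {
  edge <- edge_annotation(ddn, ego, alter)
  tab <- build_contingency(ego, alter, edge, genotypes, diagnoses)
  chi_squared_test(tab, correct = correct)
}

#' @export
print.stratification_result <- function(x, ...) {
  cat("<stratification_result> chi2 =", format_num(x$chi2),
      " p =", format_num(x$pvalue), " OR =", format_num(x$odds_ratio), "\n")
  print(x$table)
  invisible(x)
}

#' Write a stratification result as a one-row TSV
#' @param result a `stratification_result`
#' @param ego,alter phecodes, recorded in the output
#' @param path output `.tsv` path
#' @export
write_stratification <- function(result, ego, alter, path) {
  tab <- result$table
  df <- data.frame(ego = ego, alter = alter,
                   carrier_both = tab[1L, 1L], carrier_ego_only = tab[1L, 2L],
                   noncarrier_both = tab[2L, 1L], noncarrier_ego_only = tab[2L, 2L],
                   chi2 = format_num(result$chi2),
                   pvalue = format_num(result$pvalue),
                   odds_ratio = format_num(result$odds_ratio),
                   shared_snp_ids = paste(result$shared_snp_ids, collapse = ";"),
                   stringsAsFactors = FALSE)
  .write_table(df, path)
}
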