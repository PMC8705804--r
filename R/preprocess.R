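# Association-level filtering of PheWAS summary statistics and
# construction of the binary disease-SNP matrix. Defaults mirror the
# standard common-variant filtering recipe: p <= 1e-4 (inclusive),
# MAF >= 0.01, >= 200 cases, LD pruning at R^2 0.2 within 250 kb,
# male-specific phenotypes excluded, and PheCodes specified to the
# hundredth's place excluded.

#' Filtering configuration
#'
#' @param p_max keep associations with `pvalue <= p_max` (inclusive)
#' @param maf_min keep associations with `maf >= maf_min`
#' @param min_cases keep associations with `n_cases >= min_cases`
#' @param ld_r2_max LD-pruning threshold on squared dosage correlation
#' @param ld_window_kb LD-pruning window in kilobases
#' @param exclude_sex character subset of `c("male", "female")`; phenotypes
#'   whose `sex_specific` is in this set are dropped entirely
#' @param exclude_hundredths_phecodes drop phenotypes whose PheCode has two
#'   or more decimal digits (e.g. "642.11"); "642" and "642.1" are kept
#' @return a `filter_config` list
#' @export
filter_config <- function(p_max = 1e-4, maf_min = 0.01, min_cases = 200L,
                          ld_r2_max = 0.2, ld_window_kb = 250L,
                          exclude_sex = "male",
                          exclude_hundredths_phecodes = TRUE) {
  stopifnot(p_max > 0, p_max <= 1, ld_r2_max >= 0, ld_r2_max <= 1,
            ld_window_kb > 0, all(exclude_sex %in% c("male", "female")))
  structure(list(p_max = p_max, maf_min = maf_min,
                 min_cases = as.integer(min_cases),
                 ld_r2_max = ld_r2_max, ld_window_kb = as.integer(ld_window_kb),
                 exclude_sex = exclude_sex,
                 exclude_hundredths_phecodes = isTRUE(exclude_hundredths_phecodes)),
            class = "filter_config")
}

# A PheCode is "specified to the hundredth's place" when its decimal part
# has two or more digits. PheCode strings are canonical (never zero-padded),
# so a strict string test is deterministic: "642" and "642.1" pass,
# "642.11" and "642.10" do not.
is_hundredths_phecode <- function(phecode) {
  dec <- sub("^[^.]*", "", phecode)       # ".11" or ""
  nchar(dec) >= 3L
}

#' Apply association-level filters to summary statistics
#'
#' Keeps records with `pvalue <= p_max`, `maf >= maf_min` and
#' `n_cases >= min_cases` (all boundaries inclusive); drops every record of
#' phenotypes that are sex-specific for an excluded sex, and of phenotypes
#' whose PheCode is specified to the hundredth's place. Record order is
#' preserved. The three numeric filters commute, so the survivor set does
#' not depend on application order.
#'
#' @param records summary-stat data.frame ([read_summary_stats()])
#' @param phenos phenotype metadata; every record's phecode must appear
#' @param cfg a [filter_config()]
#' @return filtered data.frame of records
#' @export
filter_associations <- function(records, phenos, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  miss <- setdiff(unique(records$phecode), phenos$phecode)
  if (length(miss) > 0L)
    stop("phecode(s) missing from phenotype metadata: ",
         paste(miss, collapse = ", "), call. = FALSE)
  sex <- phenos$sex_specific[match(records$phecode, phenos$phecode)]
  keep <- records$pvalue <= cfg$p_max &
    records$maf >= cfg$maf_min &
    records$n_cases >= cfg$min_cases &
    !(sex %in% cfg$exclude_sex)
  if (cfg$exclude_hundredths_phecodes)
    keep <- keep & !is_hundredths_phecode(records$phecode)
  out <- records[keep, , drop = FALSE]
  message(sprintf("filter_associations: %d of %d records kept",
                  nrow(out), nrow(records)))
  rownames(out) <- NULL
  out
}

#' LD-prune surviving associations per phenotype
#'
#' For each phenotype, its surviving SNPs are swept greedily in ascending
#' association p-value order (ties broken by smaller position): a SNP is
#' kept iff its squared Pearson correlation of dosages with every
#' already-kept SNP on the same chromosome within `ld_window_kb` kilobases
#' is `<= ld_r2_max`. This mirrors pairwise LD pruning with p-value
#' prioritisation, so the strongest signal in each LD clump survives.
#'
#' @param records association-filtered summary-stat data.frame
#' @param genotypes a `genotype_matrix` covering all SNPs in `records`
#'   (here a synthetic cohort; any reference panel could substitute)
#' @param cfg a [filter_config()]
#' @param order_by `"pvalue"` (default) or `"pos"` for a position-first
#'   sweep
#' @param per_phenotype prune each phenotype's SNP list separately
#'   (default) or once globally on the union of surviving SNPs, using each
#'   SNP's smallest p-value across phenotypes
#' @return pruned data.frame of records
#' @export
ld_prune <- function(records, genotypes, cfg = filter_config(),
                     order_by = c("pvalue", "pos"), per_phenotype = TRUE) {
  stopifnot(inherits(cfg, "filter_config"),
            inherits(genotypes, "genotype_matrix"))
  order_by <- match.arg(order_by)
  if (nrow(records) == 0L) return(records)
  miss <- setdiff(unique(records$snp_id), genotypes$snp_ids)
  if (length(miss) > 0L)
    stop("SNP(s) absent from genotype matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)

  window_bp <- cfg$ld_window_kb * 1000
  G <- genotypes$dosages

  prune_one <- function(snp_df) {
    # snp_df: columns snp_id, chrom, pos, pvalue (one row per SNP)
    ord <- if (order_by == "pvalue") order(snp_df$pvalue, snp_df$pos)
           else order(snp_df$chrom, snp_df$pos)
    snp_df <- snp_df[ord, , drop = FALSE]
    kept <- logical(nrow(snp_df))
    for (i in seq_len(nrow(snp_df))) {
      prev <- which(kept)
      near <- prev[snp_df$chrom[prev] == snp_df$chrom[i] &
                     abs(snp_df$pos[prev] - snp_df$pos[i]) <= window_bp]
      ok <- TRUE
      if (length(near) > 0L) {
        r <- suppressWarnings(
          stats::cor(G[, snp_df$snp_id[i]], G[, snp_df$snp_id[near], drop = FALSE]))
        r[is.na(r)] <- 0      # constant dosage vector: uncorrelated
        ok <- all(r^2 <= cfg$ld_r2_max)
      }
      kept[i] <- ok
    }
    snp_df$snp_id[kept]
  }

  if (per_phenotype) {
    keep_key <- unlist(lapply(split(records, records$phecode), function(df) {
      kept <- prune_one(df[, c("snp_id", "chrom", "pos", "pvalue")])
      paste(df$phecode[1L], kept, sep = "\r")
    }), use.names = FALSE)
    out <- records[paste(records$phecode, records$snp_id, sep = "\r") %in%
                     keep_key, , drop = FALSE]
  } else {
    best <- stats::aggregate(pvalue ~ snp_id + chrom + pos, data = records, FUN = min)
    kept_snps <- prune_one(best[, c("snp_id", "chrom", "pos", "pvalue")])
    out <- records[records$snp_id %in% kept_snps, , drop = FALSE]
  }
  message(sprintf("ld_prune: %d of %d records kept", nrow(out), nrow(records)))
  rownames(out) <- NULL
  out
}

#' Build the binary disease-SNP association matrix
#'
#' One row per distinct phecode, one column per distinct SNP (both sorted
#' lexicographically); entry 1 iff a surviving association record exists.
#' Duplicate (phecode, snp_id) records collapse to a single 1. By
#' construction no all-zero row or column can remain.
#'
#' @param records filtered (and typically LD-pruned) summary-stat records
#' @return a `disease_snp_matrix`: list with `phecodes`, `snp_ids`, and the
#'   binary `assoc` matrix whose row support sets are the per-disease SNP
#'   sets used for edge annotation and carrier stratification
#' @export
build_matrix <- function(records) {
  if (nrow(records) == 0L)
    stop("no associations survive filtering", call. = FALSE)
  phe <- sort(unique(records$phecode))
  snp <- sort(unique(records$snp_id))
  A <- matrix(0L, nrow = length(phe), ncol = length(snp),
              dimnames = list(phe, snp))
  A[cbind(match(records$phecode, phe), match(records$snp_id, snp))] <- 1L
  structure(list(phecodes = phe, snp_ids = snp, assoc = A),
            class = "disease_snp_matrix")
}

#' Serialize a disease-SNP matrix as a sparse triplet TSV
#' @param matrix a `disease_snp_matrix`
#' @param path output `.tsv` path (columns `phecode`, `snp_id`)
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "disease_snp_matrix"))
  idx <- which(matrix$assoc == 1L, arr.ind = TRUE)
  df <- data.frame(phecode = matrix$phecodes[idx[, 1L]],
                   snp_id = matrix$snp_ids[idx[, 2L]],
                   stringsAsFactors = FALSE)
  df <- df[order(df$phecode, df$snp_id), , drop = FALSE]
  .write_table(df, path)
}

#' @rdname write_matrix
#' @param path path to a triplet `.tsv`
#' @export
read_matrix <- function(path) {
  df <- .read_table(path, c("phecode", "snp_id"), "association matrix")
  if (nrow(df) == 0L) stop("no associations survive filtering", call. = FALSE)
  build_matrix(data.frame(phecode = df$phecode, snp_id = df$snp_id,
                          stringsAsFactors = FALSE))
}
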