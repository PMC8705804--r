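# Readers and writers for every external table and network format the
# pipeline touches. All tabular formats are delimited text with a header
# row; the delimiter is decided by extension only (.tsv -> tab, .csv ->
# comma), never sniffed. Floats are serialized at 6 significant digits
# (scientific below 1e-4) so that outputs are diff-stable.

.delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, tsv = "\t", txt = "\t", csv = ",",
         stop("unsupported table extension '.", ext,
              "': use .tsv or .csv", call. = FALSE))
}

#' Format a numeric vector for serialization
#'
#' Fixed policy: 6 significant digits, scientific notation below 1e-4.
#' Used by every writer so that re-runs are byte-identical.
#' @param x numeric vector
#' @return character vector
#' @keywords internal
format_num <- function(x) {
  out <- formatC(x, digits = 6, format = "g")
  gsub(" ", "", out, fixed = TRUE)
}

.read_table <- function(path, required, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = .delim_for(path),
                          colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("schema error in ", what, " '", basename(path),
         "': missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

.write_table <- function(df, path) {
  utils::write.table(df, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Parse a character column to numeric; error names the column and the
# 1-based data line (header is line 1, so data row i is file line i + 1).
.parse_num <- function(x, col, path) {
  suppressWarnings(out <- as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0L) {
    stop("unparseable numeric in column '", col, "' of '", basename(path),
         "' at line ", bad[1L] + 1L, ": '", x[bad[1L]], "'", call. = FALSE)
  }
  out
}

.check_range <- function(ok, msg, path) {
  bad <- which(!ok)
  if (length(bad) > 0L) {
    stop(msg, " in '", basename(path), "' at line ", bad[1L] + 1L,
         call. = FALSE)
  }
}

#' Read a PheWAS summary-statistics table
#'
#' Expects a tab-separated file with columns `phecode`, `snp_id`, `chrom`,
#' `pos`, `pvalue`, `maf`, `n_cases`. Every row is validated: p-values must
#' lie in (0, 1], minor allele frequencies in (0, 0.5] (MAF is the *minor*
#' allele by definition), positions are 1-based, and (phecode, snp_id)
#' pairs must be unique. Row order is preserved.
#'
#' @param path path to a `.tsv` file
#' @return a `data.frame` with one row per (phenotype, variant) association
#' @seealso [write_summary_stats()]
#' @export
read_summary_stats <- function(path) {
  req <- c("phecode", "snp_id", "chrom", "pos", "pvalue", "maf", "n_cases")
  df <- .read_table(path, req, "summary stats")
  out <- data.frame(
    phecode = df$phecode,
    snp_id  = df$snp_id,
    chrom   = df$chrom,
    pos     = as.integer(.parse_num(df$pos, "pos", path)),
    pvalue  = .parse_num(df$pvalue, "pvalue", path),
    maf     = .parse_num(df$maf, "maf", path),
    n_cases = as.integer(.parse_num(df$n_cases, "n_cases", path)),
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 0L) {
    .check_range(out$pvalue > 0 & out$pvalue <= 1, "pvalue out of range (0,1]", path)
    .check_range(out$maf > 0 & out$maf <= 0.5, "maf out of range (0,0.5]", path)
    .check_range(out$pos >= 1L, "pos out of range (>= 1)", path)
    .check_range(out$n_cases >= 0L, "n_cases out of range (>= 0)", path)
    key <- paste(out$phecode, out$snp_id, sep = "\r")
    .check_range(!duplicated(key), "duplicate (phecode, snp_id) pair", path)
  }
  out
}

#' Write a summary-statistics table
#' @param records data.frame as returned by [read_summary_stats()]
#' @param path output `.tsv` path
#' @export
write_summary_stats <- function(records, path) {
  df <- records
  df$pvalue <- format_num(df$pvalue)
  df$maf <- format_num(df$maf)
  .write_table(df, path)
}

#' Read phenotype metadata
#'
#' Columns: `phecode`, `name`, `category`, `sex_specific`
#' (one of `none`, `male`, `female`). PheCodes must be unique and
#' categories non-empty.
#'
#' @param path path to a `.csv` file
#' @return data.frame of phenotype metadata
#' @export
read_phenotype_info <- function(path) {
  df <- .read_table(path, c("phecode", "name", "category", "sex_specific"),
                    "phenotype info")
  out <- df[, c("phecode", "name", "category", "sex_specific")]
  if (nrow(out) > 0L) {
    .check_range(!duplicated(out$phecode), "duplicate phecode", path)
    .check_range(nzchar(out$category), "empty category", path)
    .check_range(out$sex_specific %in% c("none", "male", "female"),
                 "sex_specific not one of none/male/female", path)
  }
  out
}

#' @rdname read_phenotype_info
#' @param info data.frame of phenotype metadata
#' @export
write_phenotype_info <- function(info, path) .write_table(info, path)

#' Read a long-format diagnosis table
#'
#' Columns: `person_id`, `code`, `code_system` (ICD9, ICD10 or PheCode).
#' Duplicate (person, code) rows are allowed on input; they are collapsed
#' later, when codes are mapped to PheCodes.
#'
#' @param path path to a `.tsv` file
#' @return data.frame of diagnosis records
#' @export
read_diagnoses <- function(path) {
  df <- .read_table(path, c("person_id", "code", "code_system"), "diagnoses")
  out <- df[, c("person_id", "code", "code_system")]
  if (nrow(out) > 0L) {
    .check_range(nzchar(out$person_id), "empty person_id", path)
    .check_range(out$code_system %in% c("ICD9", "ICD10", "PheCode"),
                 "code_system not one of ICD9/ICD10/PheCode", path)
  }
  out
}

#' @rdname read_diagnoses
#' @param records data.frame of diagnosis records
#' @export
write_diagnoses <- function(records, path) .write_table(records, path)

#' Read an ICD-to-PheCode mapping
#'
#' Columns: `icd_code`, `icd_version` (9 or 10), `phecode`. A single ICD
#' code may map to several PheCodes (one row each).
#'
#' @param path path to a `.csv` file
#' @return data.frame with one row per (ICD code, PheCode) link
#' @export
read_phecode_map <- function(path) {
  df <- .read_table(path, c("icd_code", "icd_version", "phecode"),
                    "phecode map")
  out <- data.frame(
    icd_code = df$icd_code,
    icd_version = as.integer(.parse_num(df$icd_version, "icd_version", path)),
    phecode = df$phecode,
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 0L) {
    .check_range(out$icd_version %in% c(9L, 10L), "icd_version not 9 or 10", path)
    .check_range(nzchar(out$icd_code) & nzchar(out$phecode),
                 "empty icd_code or phecode", path)
  }
  out
}

#' @rdname read_phecode_map
#' @param map data.frame mapping entries
#' @export
write_phecode_map <- function(map, path) .write_table(map, path)

#' Construct a genotype matrix object
#'
#' A person-by-SNP matrix of allele dosages in \{0, 1, 2\} with ordered
#' person and SNP identifiers. No missing dosages are allowed.
#'
#' @param dosages integer matrix, persons in rows, SNPs in columns
#' @param person_ids,snp_ids character vectors matching the matrix dims
#' @return an object of class `genotype_matrix`
#' @export
genotype_matrix <- function(dosages, person_ids, snp_ids) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(person_ids) || ncol(dosages) != length(snp_ids))
    stop("dosage matrix dimensions do not match id lists", call. = FALSE)
  if (anyDuplicated(person_ids)) stop("duplicate person_id", call. = FALSE)
  if (anyDuplicated(snp_ids)) stop("duplicate snp_id", call. = FALSE)
  if (!all(dosages %in% c(0L, 1L, 2L)))
    stop("dosage out of range: values must be 0, 1 or 2", call. = FALSE)
  storage.mode(dosages) <- "integer"
  dimnames(dosages) <- list(person_ids, snp_ids)
  structure(list(person_ids = as.character(person_ids),
                 snp_ids = as.character(snp_ids),
                 dosages = dosages),
            class = "genotype_matrix")
}

#' Read a genotype dosage matrix
#'
#' TSV layout: first column `person_id`, remaining columns one per SNP,
#' entries are dosages in \{0, 1, 2\}.
#'
#' @param path path to a `.tsv` file
#' @return a `genotype_matrix`
#' @export
read_genotypes <- function(path) {
  df <- .read_table(path, "person_id", "genotypes")
  snps <- setdiff(names(df), "person_id")
  mat <- as.matrix(df[, snps, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "integer")
  if (anyNA(mat) && nrow(df) > 0L)
    stop("unparseable dosage in '", basename(path), "'", call. = FALSE)
  genotype_matrix(mat, df$person_id, snps)
}

#' @rdname read_genotypes
#' @param geno a `genotype_matrix`
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  df <- data.frame(person_id = geno$person_ids, geno$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_table(df, path)
}

#' Write a disease-disease network to disk
#'
#' Two formats are supported. `graphml` keeps the complete object (node
#' metadata, isolated nodes, edge annotations) and round-trips exactly
#' through [read_network()]. `edge_tsv` is a flat edge list with columns
#' `phecode_a`, `phecode_b`, `weight` (cosine), `n_shared_snps`,
#' `shared_snp_ids` (semicolon-joined, sorted); rows are sorted by
#' (phecode_a, phecode_b) with `phecode_a < phecode_b`, and isolated nodes
#' are necessarily absent.
#'
#' @param ddn a `weighted_ddn` or `ego_network`
#' @param path output path
#' @param format `"graphml"` or `"edge_tsv"`
#' @export
write_network <- function(ddn, path, format = c("graphml", "edge_tsv")) {
  stopifnot(inherits(ddn, "weighted_ddn"))
  if (nrow(ddn$nodes) < 1L) stop("graph has no nodes", call. = FALSE)
  if (length(format) != 1L || !format %in% c("graphml", "edge_tsv"))
    stop("unknown network format; supported: graphml, edge_tsv", call. = FALSE)
  if (format == "edge_tsv") {
    ed <- ddn$edges
    df <- data.frame(phecode_a = ed$phecode_a, phecode_b = ed$phecode_b,
                     weight = format_num(ed$cosine_weight),
                     n_shared_snps = ed$n_shared_snps,
                     shared_snp_ids = ed$shared_snp_ids,
                     stringsAsFactors = FALSE)
    return(.write_table(df, path))
  }
  g <- as_igraph(ddn)
  ego <- if (inherits(ddn, "ego_network")) attr(ddn, "ego") else ""
  igraph::graph_attr(g, "ego") <- ego
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a network written by [write_network()]
#' @param path input path
#' @param format `"graphml"` or `"edge_tsv"`
#' @return a `weighted_ddn` (or `ego_network` if one was written as GraphML)
#' @export
read_network <- function(path, format = c("graphml", "edge_tsv")) {
  if (length(format) != 1L || !format %in% c("graphml", "edge_tsv"))
    stop("unknown network format; supported: graphml, edge_tsv", call. = FALSE)
  if (format == "edge_tsv") {
    df <- .read_table(path, c("phecode_a", "phecode_b", "weight",
                              "n_shared_snps", "shared_snp_ids"), "edge list")
    nodes <- data.frame(phecode = sort(unique(c(df$phecode_a, df$phecode_b))),
                        name = "", category = "unknown", sex_specific = "none",
                        stringsAsFactors = FALSE)
    edges <- data.frame(phecode_a = df$phecode_a, phecode_b = df$phecode_b,
                        n_shared_snps = as.integer(df$n_shared_snps),
                        cosine_weight = as.numeric(df$weight),
                        shared_snp_ids = df$shared_snp_ids,
                        stringsAsFactors = FALSE)
    return(new_weighted_ddn(nodes, edges, validate_cosine = FALSE))
  }
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(phecode = igraph::V(g)$name,
                      name = igraph::V(g)$pheno_name,
                      category = igraph::V(g)$category,
                      sex_specific = igraph::V(g)$sex_specific,
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$phecode), , drop = FALSE]
  rownames(nodes) <- NULL
  el <- igraph::as_edgelist(g)
  if (nrow(el) > 0L) {
    swap <- el[, 1L] > el[, 2L]
    tmp <- el[swap, 1L]; el[swap, 1L] <- el[swap, 2L]; el[swap, 2L] <- tmp
    edges <- data.frame(phecode_a = el[, 1L], phecode_b = el[, 2L],
                        n_shared_snps = as.integer(igraph::E(g)$n_shared_snps),
                        cosine_weight = as.numeric(igraph::E(g)$weight),
                        shared_snp_ids = igraph::E(g)$shared_snp_ids,
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$phecode_a, edges$phecode_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- empty_edge_frame()
  }
  ddn <- new_weighted_ddn(nodes, edges, validate_cosine = FALSE)
  ego <- igraph::graph_attr(g, "ego")
  if (!is.null(ego) && nzchar(ego)) ddn <- .as_ego_network(ddn, ego)
  ddn
}

#' Write GSSL score tables
#'
#' Columns: `phecode`, `raw_score`, `normalized_score`, `quartile_group`,
#' `network` (ego or full). The ego row carries an empty quartile group.
#' @param scores data.frame as produced by [gssl_score_table()]
#' @param path output `.tsv` path
#' @export
write_scores <- function(scores, path) {
  df <- scores
  df$raw_score <- format_num(df$raw_score)
  df$normalized_score <- format_num(df$normalized_score)
  .write_table(df, path)
}

#' Write per-alter comorbidity ground-truth statistics
#' @param truth data.frame as produced by [label_alters()]
#' @param path output `.tsv` path
#' @export
write_truth <- function(truth, path) {
  df <- truth
  df$phi <- format_num(df$phi)
  df$pvalue <- format_num(df$pvalue)
  .write_table(df, path)
}
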