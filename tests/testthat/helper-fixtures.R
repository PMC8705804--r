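# Shared fixture builders and independent oracles. Oracles are brute-force
# or closed-form routes kept deliberately separate from the package's
# implementation paths.

# --- fixture builders -------------------------------------------------------

make_summary_df <- function(phecode, snp_id, pvalue, maf = 0.1,
                            n_cases = 500L, chrom = "1",
                            pos = seq_along(snp_id) * 1000L) {
  data.frame(phecode = phecode, snp_id = snp_id, chrom = chrom,
             pos = as.integer(pos), pvalue = pvalue, maf = maf,
             n_cases = as.integer(n_cases), stringsAsFactors = FALSE)
}

make_pheno_df <- function(phecode, sex_specific = "none",
                          category = "circulatory system") {
  data.frame(phecode = phecode, name = paste("disease", phecode),
             category = category, sex_specific = sex_specific,
             stringsAsFactors = FALSE)
}

# disease_snp_matrix from a named list of SNP-id supports
matrix_from_supports <- function(supports) {
  recs <- data.frame(
    phecode = rep(names(supports), lengths(supports)),
    snp_id = unlist(supports, use.names = FALSE), stringsAsFactors = FALSE)
  build_matrix(recs)
}

# Fig-style toy: ego d1 with alters d2..d6 sharing 2,4,1,3,6 SNPs resp.
fig_supports <- function() {
  list(d1 = paste0("s", 1:8),
       d2 = c("s1", "s2", "s9", "s10"),
       d3 = c("s1", "s2", "s3", "s4", "s9"),
       d4 = c("s1", "s9"),
       d5 = c("s1", "s2", "s3", "s10"),
       d6 = paste0("s", 1:6))
}

# weighted_ddn straight from a symmetric weight matrix (for GSSL tests);
# the weight is stored as cosine_weight regardless of magnitude
ddn_from_weights <- function(W, codes = NULL) {
  n <- nrow(W)
  if (is.null(codes)) codes <- sprintf("d%02d", seq_len(n))
  nodes <- make_pheno_df(codes)
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  edges <- data.frame(
    phecode_a = codes[idx[, 1L]], phecode_b = codes[idx[, 2L]],
    n_shared_snps = 1L,
    cosine_weight = W[idx],
    shared_snp_ids = paste0("s", seq_len(nrow(idx))),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$phecode_a, edges$phecode_b), , drop = FALSE]
  new_weighted_ddn(nodes, edges, validate_cosine = FALSE)
}

# random connected weighted graph: a random spanning tree plus extra edges
random_connected_W <- function(n, extra = n, wmin = 0.1, wmax = 2) {
  W <- matrix(0, n, n)
  for (i in 2:n) {
    j <- sample.int(i - 1L, 1L)
    W[i, j] <- W[j, i] <- stats::runif(1, wmin, wmax)
  }
  for (k in seq_len(extra)) {
    ij <- sample.int(n, 2L)
    w <- stats::runif(1, wmin, wmax)
    W[ij[1L], ij[2L]] <- W[ij[2L], ij[1L]] <- w
  }
  W
}

# the 12-record boundary fixture used for filter-semantics checks;
# hand-derived survivor rows: 1, 3, 5, 9, 11, 12
boundary_fixture <- function() {
  recs <- make_summary_df(
    phecode = c("642", "642", "642.1", "642.1", "642.1", "642.11",
                "185", "401", "401", "250", "250", "642"),
    snp_id = paste0("rs", 1:12),
    pvalue = c(1e-4, 2e-4, 1e-5, 1e-5, 1e-5, 1e-8,
               1e-8, 1e-6, 5e-5, 0.03, 9e-5, 1e-12),
    maf = c(0.05, 0.05, 0.01, 0.009, 0.05, 0.2,
            0.2, 0.3, 0.3, 0.3, 0.1, 0.49),
    n_cases = c(500L, 500L, 500L, 500L, 200L, 1000L,
                1000L, 199L, 201L, 500L, 250L, 10000L))
  phenos <- make_pheno_df(c("642", "642.1", "642.11", "185", "401", "250"),
                          sex_specific = c("none", "none", "none", "male",
                                           "none", "none"))
  list(records = recs, phenos = phenos, survivors = c(1L, 3L, 5L, 9L, 11L, 12L))
}

# --- oracles ----------------------------------------------------------------

# dense matrix-inverse route for the propagation solve
oracle_gssl_dense <- function(W, ego_idx, mu) {
  n <- nrow(W)
  L <- diag(rowSums(W)) - W
  y <- as.numeric(seq_len(n) == ego_idx)
  as.numeric(solve(diag(n) + mu * L) %*% y)
}

# Jacobi fixed-point iteration of the propagation equations
oracle_gssl_jacobi <- function(W, ego_idx, mu, tol = 1e-13, maxit = 100000L) {
  n <- nrow(W)
  d <- rowSums(W)
  y <- as.numeric(seq_len(n) == ego_idx)
  f <- y
  for (it in seq_len(maxit)) {
    fn <- (y + mu * as.numeric(W %*% f)) / (1 + mu * d)
    if (max(abs(fn - f)) < tol) return(fn)
    f <- fn
  }
  f
}

# brute-force pairwise-concordance AUC
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# phi as the Pearson correlation of person-level indicator vectors
oracle_phi_pearson <- function(has_i, has_j) {
  suppressWarnings(stats::cor(as.numeric(has_i), as.numeric(has_j)))
}

# chi-squared via expected counts
oracle_chi2_expected <- function(tab) {
  N <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / N
  sum((tab - expected)^2 / expected)
}

# exhaustive person-level contingency count
oracle_contingency <- function(ego, alter, snps, geno, diagnoses) {
  counts <- matrix(0L, 2L, 2L,
                   dimnames = list(c("carrier", "non_carrier"),
                                   c("both_diseases", "ego_only")))
  for (p in geno$person_ids) {
    has_ego <- any(diagnoses$person_id == p & diagnoses$code == ego)
    if (!has_ego) next
    has_alt <- any(diagnoses$person_id == p & diagnoses$code == alter)
    carrier <- any(geno$dosages[p, snps] >= 1L)
    r <- if (carrier) 1L else 2L
    c_ <- if (has_alt) 1L else 2L
    counts[r, c_] <- counts[r, c_] + 1L
  }
  counts
}
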