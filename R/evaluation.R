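# Evaluation of propagation scores against comorbidity labels: AUC by the
# rank (Mann-Whitney) method with mid-ranks for ties, and Spearman rank
# correlation between scores and phi values.

#' AUC by the rank (Mann-Whitney) method
#'
#' Equivalent to the fraction of (positive, negative) pairs where the
#' positive scores higher, counting ties as 1/2; identical scores for all
#' instances therefore give 0.5. Undefined (returns `NA` with attribute
#' `undefined`) when labels are all-positive or all-negative.
#'
#' @param scores numeric vector
#' @param labels logical (or 0/1) vector of the same length
#' @return AUC in [0, 1], or `NA` when undefined
#' @export
compute_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks. The two-sided p-value uses
#' t = rho * sqrt((n-2) / (1-rho^2)) on n-2 df; for n <= 10 an exact
#' permutation p-value over all n! rank orders is available.
#'
#' @param scores,phi_values numeric vectors (>= 3 values)
#' @param exact compute the exact permutation p-value (n <= 10 only)
#' @return list with `rho` and `pvalue`
#' @export
compute_spearman <- function(scores, phi_values, exact = FALSE) {
  n <- length(scores)
  stopifnot(length(phi_values) == n, n >= 3L)
  rs <- rank(scores, ties.method = "average")
  rp <- rank(phi_values, ties.method = "average")
  if (stats::sd(rs) == 0 || stats::sd(rp) == 0)
    return(list(rho = NA_real_, pvalue = NA_real_))
  rho <- stats::cor(rs, rp)
  if (exact) {
    if (n > 10L) stop("exact permutation p-value limited to n <= 10", call. = FALSE)
    perms <- .permutations(n)
    null_rho <- apply(perms, 1L, function(p) stats::cor(rs[p], rp))
    pv <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    pv <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    pv <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, pvalue = pv)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Compare egocentric against full-network scoring across egos
#'
#' For each ego, evaluates the egocentric and the (alter-restricted) full
#' network score vectors against the phi-derived comorbidity labels:
#' AUC on the binary labels and Spearman rho against the phi values.
#' The summary averages AUC and rho over egos with a defined AUC
#' (egos with all-positive or all-negative labels are excluded and
#' flagged).
#'
#' @param pairs output of [score_all_egos()]
#' @param truths named list (by ego phecode) of [label_alters()] tables
#' @return list with `reports` (one row per ego and network type) and
#'   `summary` (one row per network type with mean AUC/rho and the number
#'   of contributing egos)
#' @export
compare_networks <- function(pairs, truths) {
  rows <- list()
  for (ego in names(pairs)) {
    p <- pairs[[ego]]
    truth <- truths[[ego]]
    if (is.null(truth)) stop("no ground truth for ego '", ego, "'", call. = FALSE)
    alters <- truth$phecode_j
    labels <- truth$is_comorbid
    phiv <- truth$phi
    for (nt in c("ego", "full")) {
      res <- if (nt == "ego") p$ego_result else p$full_result
      sc <- res$normalized_score[match(alters, res$phecode)]
      if (anyNA(sc)) stop("score missing for some alters of '", ego, "'",
                          call. = FALSE)
      auc <- compute_auc(sc, labels)
      sp <- if (length(sc) >= 3L) compute_spearman(sc, phiv)
            else list(rho = NA_real_, pvalue = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        ego = ego, network_type = nt,
        auc = as.numeric(auc),
        auc_defined = !is.na(auc),
        spearman_rho = sp$rho, spearman_pvalue = sp$pvalue,
        n_alters = length(alters), n_positive = sum(labels),
        stringsAsFactors = FALSE)
    }
  }
  reports <- do.call(rbind, rows)
  rownames(reports) <- NULL
  defined <- reports$auc_defined
  excluded <- unique(reports$ego[!defined])
  if (length(excluded) > 0L)
    message("egos excluded from averages (undefined AUC): ",
            paste(excluded, collapse = ", "))
  keep <- reports[reports$auc_defined, , drop = FALSE]
  if (nrow(keep) == 0L) {
    warning("AUC undefined for every ego; summary is empty")
    return(list(reports = reports,
                summary = data.frame(network_type = character(),
                                     mean_auc = numeric(), mean_rho = numeric(),
                                     n_egos = integer())))
  }
  summary <- do.call(rbind, lapply(split(keep, keep$network_type), function(df)
    data.frame(network_type = df$network_type[1L],
               mean_auc = mean(df$auc),
               mean_rho = mean(df$spearman_rho, na.rm = TRUE),
               n_egos = nrow(df), stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  list(reports = reports, summary = summary)
}

#' Write an evaluation report (per-ego rows plus summary rows)
#' @param cmp output of [compare_networks()]
#' @param path output `.tsv` path
#' @export
write_report <- function(cmp, path) {
  rep <- cmp$reports
  df <- rep
  if (nrow(cmp$summary) > 0L) {
    summ <- data.frame(ego = "AVERAGE", network_type = cmp$summary$network_type,
                       auc = cmp$summary$mean_auc, auc_defined = TRUE,
                       spearman_rho = cmp$summary$mean_rho,
                       spearman_pvalue = NA_real_,
                       n_alters = NA_integer_, n_positive = NA_integer_,
                       stringsAsFactors = FALSE)
    df <- rbind(rep, summ)
  }
  for (col in c("auc", "spearman_rho", "spearman_pvalue"))
    df[[col]] <- ifelse(is.na(df[[col]]), "NA", format_num(df[[col]]))
  .write_table(df, path)
}
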