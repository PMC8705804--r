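# Comorbidity ground truth from diagnosis records. Co-occurrence between
# two diseases is measured with the phi-correlation — the Pearson
# correlation of the two person-level binary disease indicators — computed
# from the 2x2 co-occurrence counts:
#
#   phi_ij = (C_ij N - P_i P_j) / sqrt(P_i P_j (N - P_i) (N - P_j))
#
# where C_ij counts persons with both diseases, P_i and P_j persons with
# each disease, and N the cohort size. A pair is labeled a true
# comorbidity iff phi > 0, p < 0.05 and C_ij > 0. Significance uses the
# standard identity chi^2 = N phi^2 on 1 df (no continuity correction);
# Fisher's exact test is available for small counts.

#' Map ICD diagnosis records to PheCodes
#'
#' Each ICD-9/ICD-10 record is expanded to all PheCodes it maps to;
#' records already in PheCode form pass through. Unmapped ICD codes are
#' dropped with a warning giving the count. Output is deduplicated on
#' (person_id, phecode): "ever had" semantics, no temporal ordering.
#'
#' @param records diagnosis data.frame ([read_diagnoses()])
#' @param map ICD-to-PheCode map ([read_phecode_map()])
#' @return diagnosis data.frame with `code_system = "PheCode"` throughout
#' @export
map_diagnoses_to_phecodes <- function(records, map) {
  if (nrow(map) == 0L) stop("empty ICD-to-PheCode map", call. = FALSE)
  icd <- records[records$code_system %in% c("ICD9", "ICD10"), , drop = FALSE]
  phe <- records[records$code_system == "PheCode", , drop = FALSE]
  out <- data.frame(person_id = phe$person_id, code = phe$code,
                    stringsAsFactors = FALSE)
  if (nrow(icd) > 0L) {
    ver <- ifelse(icd$code_system == "ICD9", 9L, 10L)
    key <- paste(icd$code, ver, sep = "\r")
    mkey <- paste(map$icd_code, map$icd_version, sep = "\r")
    hits <- split(map$phecode, mkey)
    mapped <- hits[key]
    n_unmapped <- sum(vapply(mapped, is.null, logical(1)))
    if (n_unmapped > 0L)
      warning(n_unmapped, " diagnosis record(s) with unmapped ICD codes dropped")
    n_per <- vapply(mapped, length, integer(1))
    out <- rbind(out, data.frame(
      person_id = rep(icd$person_id, n_per),
      code = unlist(mapped, use.names = FALSE),
      stringsAsFactors = FALSE))
  }
  out <- out[!duplicated(paste(out$person_id, out$code, sep = "\r")), ,
             drop = FALSE]
  out <- out[order(out$person_id, out$code), , drop = FALSE]
  rownames(out) <- NULL
  data.frame(person_id = out$person_id, code = out$code,
             code_system = rep("PheCode", nrow(out)),
             stringsAsFactors = FALSE)
}

# phi and its chi-squared p-value from the 2x2 counts. Degenerate margins
# (a disease affecting nobody or everybody) give phi = 0, p = 1.
.phi_from_counts <- function(C, Pi, Pj, N) {
  C <- as.numeric(C); Pi <- as.numeric(Pi)    # avoid integer overflow
  Pj <- as.numeric(Pj); N <- as.numeric(N)
  denom2 <- Pi * Pj * (N - Pi) * (N - Pj)
  if (denom2 <= 0) {
    return(list(phi = 0, pvalue = 1, degenerate = TRUE))
  }
  phi <- (C * N - Pi * Pj) / sqrt(denom2)
  chi2 <- N * phi^2
  list(phi = phi, pvalue = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Phi-correlation comorbidity statistic for one disease pair
#'
#' @param diagnoses PheCode diagnosis records, deduplicated on
#'   (person, code) (see [map_diagnoses_to_phecodes()])
#' @param pair character vector of two distinct phecodes
#' @param cohort_ids person universe; persons outside it are ignored, and
#'   N is its size. Sex restriction (or any other cohort definition) is
#'   the caller's responsibility.
#' @param fisher use Fisher's exact test for the p-value instead of
#'   chi^2 = N phi^2 (useful at small counts)
#' @return one-row data.frame (a `ComorbidityStat`): `phecode_i`,
#'   `phecode_j`, `C_ij`, `P_i`, `P_j`, `N`, `phi`, `pvalue`, `degenerate`,
#'   `is_comorbid`
#' @export
phi_correlation <- function(diagnoses, pair, cohort_ids, fisher = FALSE) {
  if (length(pair) != 2L || pair[1L] == pair[2L])
    stop("self-pair: need two distinct phecodes", call. = FALSE)
  N <- length(cohort_ids)
  if (N < 2L) stop("cohort must contain at least 2 persons", call. = FALSE)
  d <- diagnoses[diagnoses$person_id %in% cohort_ids, , drop = FALSE]
  who_i <- unique(d$person_id[d$code == pair[1L]])
  who_j <- unique(d$person_id[d$code == pair[2L]])
  Pi <- length(who_i); Pj <- length(who_j)
  C <- length(intersect(who_i, who_j))
  st <- .phi_from_counts(C, Pi, Pj, N)
  pv <- st$pvalue
  if (fisher && !st$degenerate) {
    tab <- matrix(c(C, Pi - C, Pj - C, N - Pi - Pj + C), 2L)
    pv <- stats::fisher.test(tab)$p.value
  }
  data.frame(phecode_i = pair[1L], phecode_j = pair[2L],
             C_ij = C, P_i = Pi, P_j = Pj, N = N,
             phi = st$phi, pvalue = pv, degenerate = st$degenerate,
             is_comorbid = st$phi > 0 & pv < 0.05 & C > 0,
             stringsAsFactors = FALSE)
}

#' Comorbidity ground truth for every alter of an egocentric network
#'
#' Computes the phi-correlation between the ego-disease and each
#' alter-disease over the given cohort. Alters never diagnosed in the
#' cohort still get a row (degenerate phi, `is_comorbid = FALSE`).
#'
#' @param net an `ego_network`
#' @param diagnoses PheCode diagnosis records
#' @param cohort_ids person universe (see [phi_correlation()])
#' @param fisher passed through to [phi_correlation()]
#' @return data.frame with one row per alter, ego first in `phecode_i`
#' @export
label_alters <- function(net, diagnoses, cohort_ids, fisher = FALSE) {
  stopifnot(inherits(net, "ego_network"))
  ego <- attr(net, "ego")
  rows <- lapply(attr(net, "alters"), function(alt)
    phi_correlation(diagnoses, c(ego, alt), cohort_ids, fisher = fisher))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
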