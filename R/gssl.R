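# Closed-form graph-based semi-supervised learning (Laplacian-regularized
# label propagation). Given a weighted undirected graph and a label vector
# y with a single 1 on the ego-disease, the score vector f minimizes
#
#     (f - y)' (f - y) + mu * f' L f,      L = D - W,  D = diag(rowSums(W))
#
# whose closed form is f = (I + mu L)^{-1} y. I + mu*L is symmetric
# positive definite, so the system is solved by a sparse Cholesky
# factorization, never an explicit inverse. On a disconnected graph the
# system decouples by connected component: components without the labeled
# node get exactly f = 0, and the scores on the labeled component sum to 1.

#' Weighted adjacency matrix of a network
#'
#' @param ddn a `weighted_ddn` or `ego_network`
#' @param weighting `"cosine"` (cosine similarity of binary association
#'   vectors) or `"count"` (number of shared SNPs)
#' @return sparse symmetric `Matrix` with rows/columns in node
#'   (phecode-sorted) order
#' @export
adjacency_matrix <- function(ddn, weighting = c("cosine", "count")) {
  stopifnot(inherits(ddn, "weighted_ddn"))
  weighting <- match.arg(weighting)
  phe <- sort(ddn$nodes$phecode)
  n <- length(phe)
  ed <- ddn$edges
  w <- if (weighting == "cosine") ed$cosine_weight else as.numeric(ed$n_shared_snps)
  i <- match(ed$phecode_a, phe)
  j <- match(ed$phecode_b, phe)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n), dimnames = list(phe, phe))
  Matrix::forceSymmetric(W)
}

#' Score diseases by closed-form label propagation
#'
#' Solves (I + mu L) f = y for the network, where y is 1 on the ego and 0
#' elsewhere, then min-max normalizes f over all nodes of the solved graph
#' (ego included) to f' in [0, 1]. Alter-diseases are stratified into
#' recommendation quartiles of the normalized score (see
#' [quartile_groups()]).
#'
#' @param graph a `weighted_ddn` or `ego_network`
#' @param ego phecode carrying the single positive label; defaults to the
#'   `ego` attribute for an `ego_network`
#' @param mu Laplacian regularization weight (> 0). Small mu pins f to the
#'   labels; large mu flattens f toward the uniform vector on the labeled
#'   component.
#' @param weighting edge weighting passed to [adjacency_matrix()]
#' @return a `gssl_result`: data.frame with columns `phecode`, `raw_score`,
#'   `normalized_score`, `is_ego`, plus attributes `mu`, `weighting`,
#'   `degree` (the Laplacian diagonal d_i)
#' @export
solve_gssl <- function(graph, ego = NULL, mu = 1.0,
                       weighting = c("cosine", "count")) {
  stopifnot(inherits(graph, "weighted_ddn"), mu > 0)
  weighting <- match.arg(weighting)
  if (is.null(ego)) {
    if (!inherits(graph, "ego_network"))
      stop("'ego' must be given for a full network", call. = FALSE)
    ego <- attr(graph, "ego")
  }
  W <- adjacency_matrix(graph, weighting)
  phe <- rownames(W)
  if (!ego %in% phe) stop("ego '", ego, "' not in graph", call. = FALSE)
  n <- length(phe)
  d <- Matrix::rowSums(W)
  y <- as.numeric(phe == ego)
  A <- Matrix::Diagonal(n, 1 + mu * d) - mu * W     # I + mu (D - W), SPD
  f <- as.numeric(Matrix::solve(A, y, sparse = TRUE))
  if (any(f == 0))
    message(sum(f == 0), " node(s) outside the labeled component scored 0")
  rng <- range(f)
  if (rng[2] - rng[1] < .Machine$double.eps * max(1, abs(rng[2]))) {
    warning("constant score vector; normalized scores set to 0")
    fn <- rep(0, n)
  } else {
    fn <- (f - rng[1]) / (rng[2] - rng[1])
  }
  res <- data.frame(phecode = phe, raw_score = f, normalized_score = fn,
                    is_ego = phe == ego, stringsAsFactors = FALSE)
  structure(res, class = c("gssl_result", "data.frame"),
            mu = mu, weighting = weighting,
            degree = stats::setNames(as.numeric(d), phe))
}

#' Stratify alter-diseases into recommendation quartiles
#'
#' Alters are ranked by normalized score descending (ties broken by
#' phecode ascending) and split into four groups by score percentile:
#' `very_high` (top quarter), `high`, `intermediate`, `low`. With n alters
#' the first three groups take ceiling(n/4) members each and `low` takes
#' the remainder.
#'
#' @param result a `gssl_result` from [solve_gssl()]
#' @return named character vector, alter phecode -> group, in rank order
#' @export
quartile_groups <- function(result) {
  stopifnot(inherits(result, "gssl_result"))
  alt <- result[!result$is_ego, , drop = FALSE]
  n <- nrow(alt)
  if (n < 1L) stop("no alter-diseases to stratify", call. = FALSE)
  if (length(unique(alt$normalized_score)) == 1L && n > 1L)
    warning("all alter scores equal; quartile grouping falls back to phecode order")
  ord <- order(-alt$normalized_score, alt$phecode)
  q <- ceiling(n / 4)
  sizes <- c(q, q, q, n - 3L * q)
  groups <- rep(c("very_high", "high", "intermediate", "low"),
                times = pmax(sizes, 0L))[seq_len(n)]
  stats::setNames(groups, alt$phecode[ord])
}

#' Score table for serialization
#'
#' Flattens a `gssl_result` into the on-disk score layout, attaching
#' quartile groups for alters (the ego row gets an empty group).
#'
#' @param result a `gssl_result`
#' @param network `"ego"` or `"full"`, recorded in the output
#' @return data.frame with columns `phecode`, `raw_score`,
#'   `normalized_score`, `quartile_group`, `network`
#' @export
gssl_score_table <- function(result, network = c("ego", "full")) {
  network <- match.arg(network)
  groups <- quartile_groups(result)
  data.frame(phecode = result$phecode,
             raw_score = result$raw_score,
             normalized_score = result$normalized_score,
             quartile_group = ifelse(result$is_ego, "",
                                     groups[result$phecode]),
             network = network,
             stringsAsFactors = FALSE)
}

#' Score a list of ego-diseases on their egocentric and on the full network
#'
#' For each ego: one propagation on its egocentric network and one on the
#' full network with the same single positive label; the full-network
#' scores are then restricted to that ego's alter set, so both conditions
#' score the same instances. Egos that are isolated in the full network
#' are skipped with a warning.
#'
#' @param ddn the full `weighted_ddn`
#' @param egos character vector of ego phecodes
#' @param mu passed to [solve_gssl()]
#' @param weighting_ego edge weighting for the egocentric solve; the
#'   egocentric similarity W' is defined as cosine similarity
#' @param weighting_full edge weighting for the full-network solve; the
#'   full network's edge weight is defined as the number of shared SNPs,
#'   so the baseline defaults to `"count"`
#' @return named list per ego with elements `ego_net` (the `ego_network`),
#'   `ego_result` (scores on the egocentric network) and `full_result`
#'   (full-network scores restricted to \{ego\} + alters, re-normalized
#'   over the full node set before restriction)
#' @export
score_all_egos <- function(ddn, egos, mu = 1.0,
                           weighting_ego = c("cosine", "count"),
                           weighting_full = c("count", "cosine")) {
  stopifnot(inherits(ddn, "weighted_ddn"))
  weighting_ego <- match.arg(weighting_ego)
  weighting_full <- match.arg(weighting_full)
  out <- list()
  for (ego in egos) {
    net <- tryCatch(extract_ego_network(ddn, ego), error = function(e) NULL)
    if (is.null(net)) {
      warning("skipping isolated or unknown ego '", ego, "'")
      next
    }
    ego_res <- solve_gssl(net, mu = mu, weighting = weighting_ego)
    full_res <- solve_gssl(ddn, ego = ego, mu = mu, weighting = weighting_full)
    keep <- full_res$phecode %in% c(ego, attr(net, "alters"))
    full_sub <- full_res[keep, , drop = FALSE]
    attr(full_sub, "mu") <- mu
    attr(full_sub, "weighting") <- weighting_full
    class(full_sub) <- class(full_res)
    out[[ego]] <- list(ego = ego, ego_net = net,
                       ego_result = ego_res, full_result = full_sub)
  }
  out
}
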