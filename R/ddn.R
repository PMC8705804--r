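# Disease-disease network construction. Nodes are phenotypes (PheCodes);
# two diseases are connected iff they share at least one significantly
# associated SNP. Each edge carries the shared SNP ids, their count, and
# the cosine similarity of the two binary association vectors:
#   w_ij = v_i . v_j / (||v_i|| ||v_j||) = |S_i ∩ S_j| / sqrt(|S_i| |S_j|).

empty_edge_frame <- function() {
  data.frame(phecode_a = character(), phecode_b = character(),
             n_shared_snps = integer(), cosine_weight = numeric(),
             shared_snp_ids = character(), stringsAsFactors = FALSE)
}

#' Construct a weighted disease-disease network object
#'
#' Low-level constructor; most users will call [build_full_ddn()]. Edges
#' are stored undirected with `phecode_a < phecode_b`, no self-loops, and
#' every edge must share at least one SNP. `shared_snp_ids` is the
#' semicolon-joined, lexicographically sorted intersection set.
#'
#' @param nodes data.frame with phenotype metadata columns
#'   (`phecode`, `name`, `category`, `sex_specific`)
#' @param edges data.frame with columns `phecode_a`, `phecode_b`,
#'   `n_shared_snps`, `cosine_weight`, `shared_snp_ids`
#' @param validate_cosine check `cosine_weight` consistency against the
#'   shared-count definition where support sizes are recoverable
#' @return an object of class `weighted_ddn`
#' @export
new_weighted_ddn <- function(nodes, edges, validate_cosine = TRUE) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (anyDuplicated(nodes$phecode)) stop("duplicate node phecode", call. = FALSE)
  if (nrow(edges) > 0L) {
    if (any(edges$phecode_a >= edges$phecode_b))
      stop("edges must satisfy phecode_a < phecode_b (no self-loops)",
           call. = FALSE)
    known <- nodes$phecode
    if (!all(c(edges$phecode_a, edges$phecode_b) %in% known))
      stop("edge endpoint not among nodes", call. = FALSE)
    if (any(edges$n_shared_snps < 1L))
      stop("every edge must share at least one SNP", call. = FALSE)
    nlisted <- lengths(strsplit(edges$shared_snp_ids, ";", fixed = TRUE))
    if (!all(nlisted == edges$n_shared_snps))
      stop("n_shared_snps does not match shared_snp_ids", call. = FALSE)
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "weighted_ddn")
}

#' Build the full disease-disease network from an association matrix
#'
#' Every pair of diseases sharing at least one associated SNP becomes an
#' edge, annotated with the shared SNP ids, their count (`n_shared_snps`,
#' the count weighting), and the cosine similarity of the binary
#' association vectors (`cosine_weight`). Diseases with no shared SNPs are
#' retained as isolated nodes.
#'
#' @param matrix a `disease_snp_matrix` from [build_matrix()]
#' @param phenos phenotype metadata (see [read_phenotype_info()]); rows for
#'   phecodes absent from the matrix are ignored
#' @return a `weighted_ddn`
#' @export
build_full_ddn <- function(matrix, phenos = NULL) {
  stopifnot(inherits(matrix, "disease_snp_matrix"))
  A <- matrix$assoc
  phe <- matrix$phecodes
  if (is.null(phenos)) {
    phenos <- data.frame(phecode = phe, name = phe, category = "unknown",
                         sex_specific = "none", stringsAsFactors = FALSE)
  }
  nodes <- phenos[match(phe, phenos$phecode), , drop = FALSE]
  if (anyNA(nodes$phecode))
    stop("phenotype metadata missing for: ",
         paste(phe[is.na(nodes$phecode)], collapse = ", "), call. = FALSE)
  shared <- tcrossprod(A)                   # |S_i ∩ S_j|
  sizes <- rowSums(A)                       # |S_i|
  norm <- sqrt(outer(sizes, sizes))
  n <- length(phe)
  edges <- empty_edge_frame()
  if (n > 1L) {
    idx <- which(upper.tri(shared) & shared > 0, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      snp_ids <- matrix$snp_ids
      shared_str <- vapply(seq_len(nrow(idx)), function(k) {
        i <- idx[k, 1L]; j <- idx[k, 2L]
        paste(sort(snp_ids[A[i, ] == 1L & A[j, ] == 1L]), collapse = ";")
      }, character(1))
      edges <- data.frame(
        phecode_a = phe[idx[, 1L]],
        phecode_b = phe[idx[, 2L]],
        n_shared_snps = as.integer(shared[idx]),
        cosine_weight = as.numeric(shared[idx] / norm[idx]),
        shared_snp_ids = shared_str,
        stringsAsFactors = FALSE)
      swap <- edges$phecode_a > edges$phecode_b
      tmp <- edges$phecode_a[swap]
      edges$phecode_a[swap] <- edges$phecode_b[swap]
      edges$phecode_b[swap] <- tmp
      edges <- edges[order(edges$phecode_a, edges$phecode_b), , drop = FALSE]
    }
  }
  new_weighted_ddn(nodes, edges)
}

.as_ego_network <- function(ddn, ego) {
  alters <- setdiff(ddn$nodes$phecode, ego)
  structure(ddn, class = c("ego_network", "weighted_ddn"),
            ego = ego, alters = sort(alters))
}

#' Extract the egocentric network of a disease
#'
#' The egocentric network is the induced subgraph on the ego-disease plus
#' all its direct neighbours (the alter-diseases, i.e. every disease
#' sharing at least one associated SNP with the ego). Alter-alter edges
#' present in the parent network are kept, so label propagation sees the
#' local topology, not just the star around the ego. Edge annotations are
#' copied unchanged from the parent.
#'
#' @param ddn a `weighted_ddn`
#' @param ego phecode of the ego-disease (must be a node of `ddn`)
#' @param star_only drop alter-alter edges (sensitivity analysis only)
#' @return an `ego_network` (subclass of `weighted_ddn`) with attributes
#'   `ego` and `alters` (alters sorted by phecode)
#' @export
extract_ego_network <- function(ddn, ego, star_only = FALSE) {
  stopifnot(inherits(ddn, "weighted_ddn"))
  if (!ego %in% ddn$nodes$phecode)
    stop("ego-disease '", ego, "' is not a node of the network", call. = FALSE)
  ed <- ddn$edges
  touches <- ed$phecode_a == ego | ed$phecode_b == ego
  alters <- sort(unique(c(ed$phecode_b[ed$phecode_a == ego],
                          ed$phecode_a[ed$phecode_b == ego])))
  if (length(alters) == 0L)
    stop("isolated ego-disease: no egocentric network for '", ego, "'",
         call. = FALSE)
  keep_nodes <- c(ego, alters)
  sub <- ed[ed$phecode_a %in% keep_nodes & ed$phecode_b %in% keep_nodes, ,
            drop = FALSE]
  if (star_only) sub <- sub[sub$phecode_a == ego | sub$phecode_b == ego, ,
                            drop = FALSE]
  nodes <- ddn$nodes[ddn$nodes$phecode %in% keep_nodes, , drop = FALSE]
  nodes <- nodes[order(nodes$phecode), , drop = FALSE]
  sub <- sub[order(sub$phecode_a, sub$phecode_b), , drop = FALSE]
  .as_ego_network(new_weighted_ddn(nodes, sub, validate_cosine = FALSE), ego)
}

#' Disease-category composition of an egocentric network
#'
#' Counts the alter-diseases (ego excluded) by disease category; counts
#' always sum to the number of alters.
#'
#' @param net an `ego_network`
#' @param phenos phenotype metadata; defaults to the metadata stored on
#'   the network's nodes
#' @return named integer vector, category -> alter count
#' @export
category_composition <- function(net, phenos = NULL) {
  stopifnot(inherits(net, "ego_network"))
  alters <- attr(net, "alters")
  if (is.null(phenos)) phenos <- net$nodes
  cat <- phenos$category[match(alters, phenos$phecode)]
  if (anyNA(cat)) stop("missing metadata for alter(s): ",
                       paste(alters[is.na(cat)], collapse = ", "), call. = FALSE)
  if (any(!nzchar(cat))) stop("empty category label", call. = FALSE)
  tab <- table(cat)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Convert a `weighted_ddn` to an igraph graph
#'
#' Node attributes: `name` (the phecode), `pheno_name`, `category`,
#' `sex_specific`, `degree`. Edge attributes: `weight` (cosine),
#' `n_shared_snps`, `shared_snp_ids`.
#' @param ddn a `weighted_ddn`
#' @return an undirected `igraph` graph
#' @export
as_igraph <- function(ddn) {
  stopifnot(inherits(ddn, "weighted_ddn"))
  verts <- data.frame(name = ddn$nodes$phecode,
                      pheno_name = ddn$nodes$name,
                      category = ddn$nodes$category,
                      sex_specific = ddn$nodes$sex_specific,
                      stringsAsFactors = FALSE)
  ed <- ddn$edges
  el <- data.frame(from = ed$phecode_a, to = ed$phecode_b,
                   weight = ed$cosine_weight,
                   n_shared_snps = ed$n_shared_snps,
                   shared_snp_ids = ed$shared_snp_ids,
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = verts)
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' @export
print.weighted_ddn <- function(x, ...) {
  cat("<weighted_ddn> ", nrow(x$nodes), " diseases, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' @export
print.ego_network <- function(x, ...) {
  cat("<ego_network> ego ", attr(x, "ego"), ": ",
      length(attr(x, "alters")), " alters, ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

#' Look up the edge annotation for a disease pair
#' @param ddn a `weighted_ddn`
#' @param a,b phecodes of the two diseases
#' @return one-row data.frame (the edge), or an error if not connected
#' @export
edge_annotation <- function(ddn, a, b) {
  stopifnot(inherits(ddn, "weighted_ddn"))
  lo <- min(a, b); hi <- max(a, b)
  hit <- ddn$edges[ddn$edges$phecode_a == lo & ddn$edges$phecode_b == hi, ,
                   drop = FALSE]
  if (nrow(hit) == 0L)
    stop("no edge between '", a, "' and '", b, "'", call. = FALSE)
  hit
}

#' SNP ids on an edge, as a character vector
#' @param edge one-row edge data.frame from [edge_annotation()]
#' @return character vector of shared SNP ids
#' @export
shared_snps <- function(edge) {
  strsplit(edge$shared_snp_ids[1L], ";", fixed = TRUE)[[1L]]
}
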