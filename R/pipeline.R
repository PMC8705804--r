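# End-to-end orchestration: simulate -> scan -> filter -> network ->
# per-ego scoring and ground truth -> evaluation -> stratification. Every
# stage reads and writes plain files, so each is also consumable
# standalone; run_all() wires them together and records a manifest.

# Stage-level sub-seeds derived from the one global seed by hashing the
# stage name, so a stage rerun in isolation reproduces its in-pipeline
# draw. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + h * 7919) %% 2147483646 + 1)
}

#' Reference simulation configuration
#'
#' The package's fixed desk-scale world: 5,000 individuals, 500 SNPs on
#' one chromosome, 15 diseases of which three (PheCodes 101-103) are
#' designated ego-diseases. Pleiotropy blocks plant ego-alter causal
#' overlaps of 10 SNPs (alters 104-106) and 5 SNPs (alters 107-112); the
#' strong alters are additionally hub diseases, each sharing 10 causal
#' SNPs with the two background diseases 113 and 114; disease 115 is
#' unconnected. All remaining pairs share 0 causal SNPs. Effect size 0.5
#' per standardized allele, prevalence 10%, EHR-like diagnosis noise
#' (sensitivity 0.65, specificity 0.98), MAF Uniform(0.02, 0.2).
#'
#' @param seed RNG seed for the cohort draw
#' @return a `sim_config`
#' @export
reference_config <- function(seed = 1L) {
  blocks <- list()
  for (i in 1:3) {
    blocks <- c(blocks, list(
      list(diseases = c(i, 3L + i), n_shared = 10L),
      list(diseases = c(i, 6L + i), n_shared = 5L),
      list(diseases = c(i, 9L + i), n_shared = 5L),
      list(diseases = c(3L + i, 13L), n_shared = 10L),
      list(diseases = c(3L + i, 14L), n_shared = 10L)))
  }
  simulation_config(
    n_individuals = 5000L, n_snps = 500L, n_diseases = 15L,
    maf_low = 0.02, maf_high = 0.2, causal_per_disease = 30L,
    pleiotropy_blocks = blocks, effect_size = 0.5, prevalence = 0.1,
    diagnosis_sensitivity = 0.65, diagnosis_specificity = 0.98,
    seed = seed)
}

#' Ego-diseases of the reference world
#' @return character vector of the three designated ego phecodes
#' @export
reference_egos <- function() c("101", "102", "103")

#' Pipeline configuration
#'
#' @param sim a [simulation_config()]
#' @param filter a [filter_config()]
#' @param egos non-empty character vector of ego phecodes
#' @param mu propagation regularization weight
#' @param weighting_ego,weighting_full edge weightings (see
#'   [score_all_egos()])
#' @param strat_pair length-2 character vector (ego, alter) for the
#'   individual-level stratification stage, or NULL to pick the first
#'   connected ego-alter pair
#' @param seed global seed, expanded into per-stage sub-seeds
#' @param out_dir output directory (created if absent)
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(sim, filter = filter_config(), egos,
                            mu = 1.0, weighting_ego = "cosine",
                            weighting_full = "count",
                            strat_pair = NULL, seed = 1L, out_dir) {
  stopifnot(inherits(sim, "sim_config"), inherits(filter, "filter_config"))
  if (length(egos) < 1L) stop("ego list must be non-empty", call. = FALSE)
  if (!is.null(strat_pair) && length(strat_pair) != 2L)
    stop("strat_pair must be a (ego, alter) pair", call. = FALSE)
  structure(list(sim = sim, filter = filter, egos = egos, mu = mu,
                 weighting_ego = weighting_ego,
                 weighting_full = weighting_full,
                 strat_pair = strat_pair, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> association scan -> filtering and LD pruning ->
#' full network -> per-ego (egocentric network, propagation scores,
#' comorbidity ground truth) -> evaluation -> stratification, writing
#' every artifact under `config$out_dir` plus a `manifest.json` listing
#' the configuration, seed, package version and MD5 of every output.
#' Identical config and seed reproduce byte-identical outputs.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list with the in-memory stage results
#'   (`cohort`, `ddn`, `pairs`, `truths`, `comparison`, `stratification`)
#'   and `files` (named vector of artifact paths)
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character()
  emit <- function(name) files[[name]] <<- out(name)

  message("stage simulate")
  sim <- config$sim
  sim$seed <- derive_seed(config$seed, "simulate")
  cohort <- simulate_cohort(sim)
  write_genotypes(cohort$genotypes, out("genotypes.tsv")); emit("genotypes.tsv")
  write_phenotype_info(cohort$phenotype_info, out("phenotype_info.csv"))
  emit("phenotype_info.csv")
  write_causal_sets(cohort, out("truth_causal_sets.tsv"))
  emit("truth_causal_sets.tsv")
  writeLines(cohort$genotypes$person_ids, out("cohort_ids.txt"))
  emit("cohort_ids.txt")

  message("stage scan")
  stats <- association_scan(cohort)
  write_summary_stats(stats, out("summary_stats.tsv")); emit("summary_stats.tsv")

  message("stage diagnose")
  diagnoses <- emit_diagnoses(cohort, seed = derive_seed(config$seed, "diagnose"))
  write_diagnoses(diagnoses, out("diagnoses.tsv")); emit("diagnoses.tsv")

  message("stage preprocess")
  kept <- filter_associations(stats, cohort$phenotype_info, config$filter)
  kept <- ld_prune(kept, cohort$genotypes, config$filter)
  mat <- build_matrix(kept)
  write_matrix(mat, out("matrix.tsv")); emit("matrix.tsv")

  message("stage network")
  ddn <- build_full_ddn(mat, cohort$phenotype_info)
  write_network(ddn, out("ddn.graphml"), "graphml"); emit("ddn.graphml")

  message("stage score")
  pairs <- score_all_egos(ddn, config$egos, mu = config$mu,
                          weighting_ego = config$weighting_ego,
                          weighting_full = config$weighting_full)
  if (length(pairs) == 0L)
    stop("stage score: no ego produced an egocentric network", call. = FALSE)
  truths <- list()
  for (ego in names(pairs)) {
    p <- pairs[[ego]]
    write_network(p$ego_net, out(sprintf("ego_%s.graphml", ego)), "graphml")
    emit(sprintf("ego_%s.graphml", ego))
    sc <- rbind(gssl_score_table(p$ego_result, "ego"),
                gssl_score_table(p$full_result, "full"))
    write_scores(sc, out(sprintf("scores_%s.tsv", ego)))
    emit(sprintf("scores_%s.tsv", ego))
    truths[[ego]] <- label_alters(p$ego_net, diagnoses,
                                  cohort$genotypes$person_ids)
    write_truth(truths[[ego]], out(sprintf("truth_%s.tsv", ego)))
    emit(sprintf("truth_%s.tsv", ego))
  }

  message("stage evaluate")
  comparison <- compare_networks(pairs, truths)
  write_report(comparison, out("report.tsv")); emit("report.tsv")

  message("stage stratify")
  strat <- NULL
  pair <- config$strat_pair
  if (is.null(pair)) {
    first_net <- pairs[[1L]]
    pair <- c(first_net$ego, attr(first_net$ego_net, "alters")[1L])
  }
  strat <- tryCatch(
    stratify_pair(ddn, pair[1L], pair[2L], cohort$genotypes, diagnoses),
    error = function(e) {
      warning("stage stratify failed: ", conditionMessage(e))
      NULL
    })
  if (!is.null(strat)) {
    write_stratification(strat, pair[1L], pair[2L], out("strat.tsv"))
    emit("strat.tsv")
  }

  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- list(
      tool = "egoddn",
      version = as.character(utils::packageVersion("egoddn")),
      seed = config$seed,
      mu = config$mu,
      weighting_ego = config$weighting_ego,
      weighting_full = config$weighting_full,
      egos = config$egos,
      sim = unclass(config$sim),
      filter = unclass(config$filter),
      files = as.list(tools::md5sum(unlist(files))))
    names(manifest$files) <- basename(names(manifest$files))
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files[["manifest.json"]] <- out("manifest.json")
  } else {
    warning("jsonlite not available; manifest.json not written")
  }

  invisible(list(cohort = cohort, ddn = ddn, pairs = pairs, truths = truths,
                 comparison = comparison, stratification = strat,
                 files = files))
}
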