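# Evaluation of a genome-wide prioritization: ROC/AUC for recovery of
# known control targets, fold enrichment in a top-K list, rank-score
# summaries, and extraction of the induced interaction subnetwork among
# top-ranked proteins.

#' ROC curve and AUC for recovering control targets
#'
#' Final scores are averaged genome-wide ranks, low = best.  The ROC sweeps
#' a threshold over the score, grouping tied scores; the AUC is computed by
#' the tie-corrected rank-sum identity (which equals the trapezoid area of
#' the tie-grouped ROC).
#'
#' @param scores Tibble with `protein_id` and `final_score` (low = best),
#'   e.g. `result$scores` from [nested_cv_prioritize()].
#' @param positives Integer vector of control-target protein ids.
#' @return List with `roc` (tibble `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, positives) {
  positives <- unique(as.integer(positives))
  if (!length(positives)) abort("No positive controls supplied.")
  lab <- scores$protein_id %in% positives
  if (!any(lab)) abort("No positive control appears in the score table.")
  pred <- -scores$final_score  # high = better candidate
  ord <- order(pred, decreasing = TRUE)
  lab <- lab[ord]
  pred <- pred[ord]
  grp_last <- !duplicated(pred, fromLast = TRUE)  # last index of each tie block
  tp <- cumsum(lab)[grp_last]
  fp <- cumsum(!lab)[grp_last]
  roc <- tibble(
    fpr = c(0, fp / sum(!lab)),
    tpr = c(0, tp / sum(lab))
  )
  auc <- auc_rank(pred, lab)
  list(roc = roc, auc = auc)
}

#' Fold enrichment of control targets in a top-K list
#'
#' Observed-over-expected ratio: the fraction of the top `k` that are
#' controls divided by the genome-wide control fraction,
#' `(hits/k) / (n_positives/n_universe)`.
#'
#' @param hits Number of control targets among the top `k`.
#' @param k Size of the top list.
#' @param n_positives Total control targets in the universe.
#' @param n_universe Universe size.
#' @return The enrichment factor (0 when `hits` is 0).
#' @export
fold_enrichment <- function(hits, k, n_positives, n_universe) {
  stopifnot(k >= 1, k <= n_universe, hits <= k, n_positives >= 1)
  (hits / k) / (n_positives / n_universe)
}

#' Fold enrichment computed from a score table
#'
#' Counts control targets in the top `k` of the prioritization (ascending
#' final score; ties broken by protein id for determinism) and applies
#' [fold_enrichment()].  Depends only on score ranks, not on their scale.
#'
#' @inheritParams roc_auc
#' @param k Size of the top list.
#' @return List with `hits` and `enrichment`.
#' @export
top_k_enrichment <- function(scores, positives, k) {
  top <- head(scores$protein_id[order(scores$final_score, scores$protein_id)], k)
  hits <- length(intersect(top, unique(as.integer(positives))))
  list(hits = hits,
       enrichment = fold_enrichment(hits, k, length(unique(positives)),
                                    nrow(scores)))
}

#' Rank-score summary of the top-K prioritized proteins
#'
#' @inheritParams roc_auc
#' @param k Size of the top list.
#' @return Tibble `mean`, `median`, `min`, `max` of the `k` best final
#'   scores.
#' @export
rank_summary <- function(scores, k) {
  stopifnot(k >= 1)
  best <- sort(scores$final_score)[seq_len(min(k, nrow(scores)))]
  tibble(mean = mean(best), median = median(best),
         min = min(best), max = max(best))
}

#' Induced interaction subnetwork of the top-K proteins
#'
#' Direct physical interactions connecting proteins of the top-K list, with
#' effect and mechanism labels preserved.
#'
#' @param kb An `mcl_kb`.
#' @inheritParams roc_auc
#' @param k Size of the top list.
#' @return Interaction tibble restricted to pairs within the top `k`.
#' @export
extract_top_subnetwork <- function(kb, scores, k) {
  top <- head(scores$protein_id[order(scores$final_score, scores$protein_id)], k)
  filter(kb$interactions, .data$source %in% top & .data$target %in% top)
}

#' Run the full prioritization pipeline and write its artifacts
#'
#' Simulate (or load) a knowledge base, compute all evidence features,
#' integrate them by nested cross-validated PLS, evaluate recovery of the
#' positive controls, extract the top-K subnetwork, functionally annotate
#' the top-K list against the pathway-map collection, and write every
#' artifact plus a manifest to `out_dir`.  Fully deterministic given the
#' two configs.
#'
#' @param out_dir Output directory (created).
#' @param synth An `mcl_synth_config`; ignored when `kb_dir` is given.
#' @param cv An `mcl_cv_config`.
#' @param kb_dir Optional directory of an existing knowledge base written
#'   by [write_kb()]; replaces simulation.
#' @param k_top Size of the reported top target list (default 250).
#' @return Invisibly, a list with the knowledge base, prioritization result
#'   and evaluation report.
#' @export
run_pipeline <- function(out_dir, synth = synth_config(), cv = cv_config(),
                         kb_dir = NULL, k_top = 250L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(kb_dir)) {
    gen <- generate_kb(synth)
    kb <- gen$kb
    truth <- gen$truth
    write_kb(kb, file.path(out_dir, "kb"))
    jsonlite::write_json(
      list(planted_targets = truth$planted_targets),
      file.path(out_dir, "truth.json")
    )
  } else {
    kb <- read_kb(kb_dir)
    truth <- NULL
  }
  positives <- define_positive_controls(kb)
  features <- build_feature_matrix(kb)
  result <- nested_cv_prioritize(features, positives, cv)

  ranked <- tidy(result)
  readr::write_tsv(ranked, file.path(out_dir, "ranked_targets.tsv"), progress = FALSE)
  readr::write_tsv(result$selection_counts,
                   file.path(out_dir, "feature_selection_counts.tsv"), progress = FALSE)
  readr::write_tsv(result$error_curve,
                   file.path(out_dir, "error_curve.tsv"), progress = FALSE)

  k_top <- min(k_top, nrow(ranked))
  ev <- roc_auc(result$scores, positives)
  enr <- top_k_enrichment(result$scores, positives, k_top)
  rsum <- rank_summary(result$scores, k_top)
  report <- list(
    auc = ev$auc,
    roc = ev$roc,
    k = k_top,
    hits_in_top_k = enr$hits,
    fold_enrichment = enr$enrichment,
    rank_summary = rsum
  )
  subnet <- extract_top_subnetwork(kb, result$scores, k_top)
  readr::write_tsv(subnet, file.path(out_dir, "top_subnetwork.tsv"), progress = FALSE)
  top_ids <- head(ranked$protein_id, k_top)
  annot <- enrich_terms(top_ids, kb$pathway_maps)
  readr::write_tsv(annot, file.path(out_dir, "top_enrichment.tsv"), progress = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mclprio")),
    synth_config_hash = rlang::hash(unclass(synth)),
    cv_config_hash = rlang::hash(unclass(cv)),
    synth_seed = synth$rng_seed,
    cv_seed = cv$rng_seed,
    n_proteins = nrow(kb$proteins),
    n_positives = length(positives),
    recovery_auc = ev$auc,
    hits_in_top_k = enr$hits,
    fold_enrichment = enr$enrichment,
    k_top = k_top
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(kb = kb, truth = truth, result = result, report = report))
}
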