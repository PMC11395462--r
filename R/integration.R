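# Evidence integration: feature-matrix assembly, PLS classification inside
# a balanced nested cross-validation with recursive feature elimination,
# and genome-wide rank averaging across repeats.

#' Cross-validation configuration for evidence integration
#'
#' @param outer_folds,inner_folds Fold counts of the nested cross-validation
#'   (both 5 by default).
#' @param repeats Number of full cross-validation repeats (default 10; with
#'   5 outer folds this gives the 0-50 feature-selection count range).
#' @param neg_pos_ratio Negatives sampled per positive in each outer fold
#'   (default 10).
#' @param pls_components PLS latent components (default 2).
#' @param rfe_step Features eliminated per recursive-elimination step.
#' @param error_metric Inner-validation prediction error: `"one_minus_auc"`
#'   (threshold-free, default) or `"misclassification"`.
#' @param rng_seed Seed governing fold splits and negative sampling.
#' @return A list of class `mcl_cv_config`.
#' @export
cv_config <- function(outer_folds = 5L, inner_folds = 5L, repeats = 10L,
                      neg_pos_ratio = 10L, pls_components = 2L,
                      rfe_step = 1L,
                      error_metric = c("one_minus_auc", "misclassification"),
                      rng_seed = 1L) {
  error_metric <- match.arg(error_metric)
  stopifnot(outer_folds >= 2, inner_folds >= 2, repeats >= 1,
            neg_pos_ratio >= 1, pls_components >= 1, rfe_step >= 1)
  structure(as.list(environment()), class = "mcl_cv_config")
}

#' Assemble the evidence feature matrix
#'
#' Joins the per-disorder knowledge scores, the global consortium count,
#' the network scores and the similar-disease binaries into one proteins x
#' features table.  Raw values are stored; standardization happens inside
#' the modeling step.  Column provenance (evidence module and disorder) is
#' attached as attribute `"provenance"`.
#'
#' @param kb An `mcl_kb`.
#' @param knowledge,network,similarity Optional precomputed blocks (outputs
#'   of [score_knowledge()], [score_network()], [score_similarity()]); each
#'   must cover exactly the knowledge base's protein universe.
#' @param per_disorder_network Seed the four network scores per disorder
#'   (columns `<disorder>.net.*`) instead of once with pooled biomarkers.
#' @param similar_k,min_shared Similar-disease selection controls.
#' @return Tibble with `protein_id` and one column per feature.
#' @export
build_feature_matrix <- function(kb, knowledge = NULL, network = NULL,
                                 similarity = NULL,
                                 per_disorder_network = FALSE,
                                 similar_k = 15L, min_shared = 3L) {
  universe <- protein_universe(kb)
  check_universe <- function(block, what) {
    if (!identical(block$protein_id, universe)) {
      abort(paste0("Feature block '", what,
                   "' does not cover the knowledge-base universe."))
    }
    block
  }
  knowledge <- check_universe(knowledge %||% score_knowledge(kb), "knowledge")
  if (is.null(network)) {
    network <- if (per_disorder_network) {
      blocks <- map(kb$disorders$disorder, function(d) {
        b <- score_network(kb, seeds = kb$disorders$biomarkers[[
          match(d, kb$disorders$disorder)]])
        names(b)[-1] <- paste0(d, ".", names(b)[-1])
        b
      })
      purrr::reduce(blocks, left_join, by = "protein_id")
    } else {
      score_network(kb)
    }
  }
  network <- check_universe(network, "network")
  similarity <- similarity %||%
    score_similarity(kb, k = similar_k, min_shared = min_shared)$features
  similarity <- check_universe(similarity, "similarity")

  out <- left_join(knowledge, network, by = "protein_id")
  out <- left_join(out, similarity, by = "protein_id")
  cols <- setdiff(names(out), "protein_id")
  provenance <- tibble(
    column = cols,
    module = dplyr::case_when(
      grepl("^net\\.|\\.net\\.", cols) ~ "network",
      grepl("^sim\\.", cols) ~ "similarity",
      cols == "metaminer.count" ~ "knowledge",
      TRUE ~ "knowledge"
    ),
    disorder = ifelse(
      grepl("^(net|sim|metaminer)\\.", cols), NA_character_,
      sub("\\..*$", "", cols)
    )
  )
  attr(out, "provenance") <- provenance
  out
}

#' Sample negative controls
#'
#' Uniform sample, without replacement, of proteins that are not positive
#' controls; size is `ratio` times the number of positives.  Called afresh
#' in every outer fold so the effect of the random choice averages out.
#'
#' @param universe Integer vector of all protein ids.
#' @param positives Integer vector of positive-control ids.
#' @param ratio Negatives per positive (default 10).
#' @return Integer vector of negative-control ids.
#' @export
sample_negatives <- function(universe, positives, ratio = 10L) {
  pool <- setdiff(universe, positives)
  n_neg <- ratio * length(positives)
  if (length(pool) < n_neg) {
    abort(sprintf("Need %d negatives but only %d non-positive proteins exist.",
                  n_neg, length(pool)))
  }
  resample(pool, n_neg)
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- resample(rep_len(seq_len(k), length(idx)), length(idx))
  }
  fold
}

prediction_error <- function(scores, labels, metric) {
  if (metric == "misclassification") {
    mean((scores >= 0.5) != (labels > 0))
  } else {
    1 - auc_rank(scores, labels)
  }
}

#' Recursive feature elimination with an inner cross-validation
#'
#' Starting from the full feature set, repeatedly drops the feature(s) with
#' the smallest mean absolute PLS coefficient (on standardized inputs)
#' across the inner folds, recording the inner-validation prediction error
#' at each feature count.  Elimination stops once only `pls_components`
#' features remain.  Returns the feature set minimizing the error; ties are
#' broken toward fewer features.
#'
#' @param x Numeric matrix (training samples x standardized features).
#' @param y Binary labels (1 = positive control).
#' @param config An `mcl_cv_config`.
#' @return List with `selected` (character vector of retained features) and
#'   `curve` (tibble `n_features`, `error`).
#' @export
rfe_inner_loop <- function(x, y, config = cv_config()) {
  stopifnot(is.matrix(x), !is.null(colnames(x)), length(y) == nrow(x))
  fold <- stratified_folds(y, config$inner_folds)
  current <- colnames(x)
  sets <- list()
  errors <- numeric()
  repeat {
    ncomp <- min(config$pls_components, length(current))
    fold_err <- numeric()
    importance <- numeric(length(current))
    n_fits <- 0L
    for (f in seq_len(config$inner_folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
      fit <- pls1_fit(x[tr, current, drop = FALSE], y[tr], ncomp)
      pred <- pls1_predict(fit, x[!tr, current, drop = FALSE])
      fold_err <- c(fold_err, prediction_error(pred, y[!tr], config$error_metric))
      importance <- importance + abs(fit$coef)
      n_fits <- n_fits + 1L
    }
    if (n_fits == 0L) abort("Degenerate labels: no inner fold had both classes.")
    sets[[length(sets) + 1L]] <- current
    errors[length(errors) + 1L] <- mean(fold_err)
    if (length(current) <= config$pls_components) break
    n_drop <- min(config$rfe_step, length(current) - config$pls_components)
    drop <- current[order(importance / n_fits)[seq_len(n_drop)]]
    current <- setdiff(current, drop)
  }
  best <- which(errors == min(errors))
  best <- best[length(best)]  # ties: later step = fewer features
  list(
    selected = sets[[best]],
    curve = tibble(n_features = lengths(sets), error = errors)
  )
}

#' Nested cross-validated genome-wide target prioritization
#'
#' Per repeat: positive controls are split into stratified outer folds; in
#' each outer fold negatives are freshly sampled, recursive feature
#' elimination runs in the inner cross-validation, a PLS model is fit on
#' the selected features, and all proteins are scored genome-wide.  A
#' protein's per-repeat score averages only the fold models that did not
#' train on it, so labeled proteins are always scored out of fold.  Scores
#' are converted to genome-wide ranks (1 = best, ties averaged) and ranks
#' are averaged across repeats into the final prioritization.
#'
#' @param features Feature tibble from [build_feature_matrix()].
#' @param positives Integer vector of positive-control protein ids.
#' @param config An `mcl_cv_config`.
#' @return An object of class `mcl_prioritization`: final averaged ranks,
#'   per-repeat rank matrix, per-feature selection counts (at most
#'   `repeats * outer_folds`), and the aggregated prediction-error curve.
#' @export
nested_cv_prioritize <- function(features, positives, config = cv_config()) {
  stopifnot(inherits(config, "mcl_cv_config"))
  ids <- features$protein_id
  positives <- sort(unique(as.integer(positives)))
  if (!all(positives %in% ids)) abort("Positives must lie in the feature universe.")
  if (length(positives) < config$outer_folds) {
    abort("Fewer positives than outer folds.")
  }
  x_raw <- as.matrix(features[setdiff(names(features), "protein_id")])
  sds <- apply(x_raw, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("Dropping %d constant feature column(s): %s",
                 sum(sds == 0),
                 paste(colnames(x_raw)[sds == 0], collapse = ", ")))
    x_raw <- x_raw[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  x <- scale(x_raw)
  n <- nrow(x)
  feature_names <- colnames(x)
  set.seed(config$rng_seed)

  rank_mat <- matrix(NA_real_, n, config$repeats)
  sel_counts <- setNames(numeric(length(feature_names)), feature_names)
  curves <- list()
  pos_idx <- match(positives, ids)

  for (rep_i in seq_len(config$repeats)) {
    pos_fold <- stratified_folds(rep(1, length(positives)), config$outer_folds)
    score_sum <- numeric(n)
    score_cnt <- integer(n)
    score_all <- numeric(n)
    for (f in seq_len(config$outer_folds)) {
      train_pos <- positives[pos_fold != f]
      negs <- sample_negatives(ids, positives, config$neg_pos_ratio)
      train_ids <- c(train_pos, negs)
      tr_idx <- match(train_ids, ids)
      y <- c(rep(1, length(train_pos)), rep(0, length(negs)))
      rfe <- rfe_inner_loop(x[tr_idx, , drop = FALSE], y, config)
      curves[[length(curves) + 1L]] <- rfe$curve
      sel_counts[rfe$selected] <- sel_counts[rfe$selected] + 1
      fit <- pls1_fit(x[tr_idx, rfe$selected, drop = FALSE], y,
                      config$pls_components)
      pred <- pls1_predict(fit, x[, rfe$selected, drop = FALSE])
      held_out <- !(seq_len(n) %in% tr_idx)
      score_sum[held_out] <- score_sum[held_out] + pred[held_out]
      score_cnt[held_out] <- score_cnt[held_out] + 1L
      score_all <- score_all + pred / config$outer_folds
    }
    s <- ifelse(score_cnt > 0, score_sum / pmax(score_cnt, 1L), score_all)
    rank_mat[, rep_i] <- rank(-s, ties.method = "average")
  }

  curve <- bind_rows(curves)
  curve <- summarise(group_by(curve, .data$n_features),
                     error = mean(.data$error), .groups = "drop")
  curve <- arrange(curve, dplyr::desc(.data$n_features))

  structure(
    list(
      scores = tibble(protein_id = ids, final_score = rowMeans(rank_mat)),
      rank_matrix = rank_mat,
      selection_counts = tibble(feature = feature_names,
                                count = unname(sel_counts)),
      error_curve = curve,
      positives = positives,
      config = config,
      n_proteins = n
    ),
    class = "mcl_prioritization"
  )
}

#' @method print mcl_prioritization
#' @export
print.mcl_prioritization <- function(x, ...) {
  cat("<mcl_prioritization>\n")
  cat("  proteins:   ", x$n_proteins, "\n")
  cat("  positives:  ", length(x$positives), "\n")
  cat("  repeats:    ", x$config$repeats, "x", x$config$outer_folds, "outer folds\n")
  cat("  recovery AUC:", round(roc_auc(x$scores, x$positives)$auc, 3), "\n")
  invisible(x)
}

#' Tidy a prioritization result
#'
#' @param x An `mcl_prioritization`.
#' @param ... Unused.
#' @return Tibble `protein_id`, `final_score` (averaged genome-wide rank,
#'   low = best), `rank` (position after sorting) and `is_positive`.
#' @export
tidy.mcl_prioritization <- function(x, ...) {
  out <- mutate(x$scores,
                is_positive = .data$protein_id %in% x$positives)
  out <- arrange(out, .data$final_score, .data$protein_id)
  mutate(out, rank = row_number())
}

#' One-row summary of a prioritization result
#'
#' @param x An `mcl_prioritization`.
#' @param ... Unused.
#' @return Tibble with problem sizes, the cross-validated recovery AUC and
#'   the error-minimizing feature count.
#' @export
glance.mcl_prioritization <- function(x, ...) {
  best <- x$error_curve$n_features[which.min(x$error_curve$error)]
  tibble(
    n_proteins = x$n_proteins,
    n_features = nrow(x$selection_counts),
    n_positives = length(x$positives),
    repeats = x$config$repeats,
    outer_folds = x$config$outer_folds,
    recovery_auc = roc_auc(x$scores, x$positives)$auc,
    best_n_features = best
  )
}
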