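# Disease-similarity features: candidate diseases are ranked by the
# hypergeometric significance of their gene-set overlap with the MCL
# reference set, the top k passing a minimum shared-target rule are
# selected, and each selected disease contributes one binary
# is-a-target-there feature column.

#' Hypergeometric disease similarity
#'
#' Similarity between two gene sets drawn from a common universe, defined
#' as \eqn{-\log_{10} P(X \ge |A \cap B|)} under the hypergeometric null.
#' Symmetric in `A` and `B`; clamped at 0 so near-independent overlaps never
#' score negative.
#'
#' @param set_a,set_b Integer vectors of gene ids.
#' @param universe_size Size of the common universe.
#' @return Single non-negative similarity value.
#' @export
disease_similarity <- function(set_a, set_b, universe_size) {
  set_a <- unique(as.integer(set_a)); set_b <- unique(as.integer(set_b))
  if (!length(set_a) || !length(set_b)) {
    warn("Empty gene set: disease similarity is 0.")
    return(0)
  }
  if (max(length(set_a), length(set_b)) > universe_size) {
    abort("Gene sets cannot be larger than the universe.")
  }
  ov <- length(intersect(set_a, set_b))
  p <- hypergeom_tail(ov, length(set_a), length(set_b), universe_size)
  max(-log10(max(p, P_FLOOR)), 0)
}

#' Select the most similar diseases
#'
#' Ranks candidate disease gene sets by [disease_similarity()] to a
#' reference set (typically the pooled gold-standard targets) and returns
#' the top `k` among candidates sharing at least `min_shared` genes with
#' the reference.  Ties in similarity break lexicographically by name.
#'
#' @param candidates Gene-set tibble of candidate disease target sets.
#' @param reference Integer vector: the reference (gold-standard) gene set.
#' @param universe_size Common universe size.
#' @param k Number of diseases to select (default 15).
#' @param min_shared Minimum genes shared with the reference (default 3).
#' @return Tibble `disease`, `overlap`, `similarity`, `selected`, ordered
#'   by decreasing similarity among eligible diseases first.
#' @export
select_similar_diseases <- function(candidates, reference, universe_size,
                                    k = 15L, min_shared = 3L) {
  reference <- unique(as.integer(reference))
  rec <- tibble(
    disease = candidates$name,
    overlap = map_int(candidates$members, function(m) {
      length(intersect(unique(as.integer(m)), reference))
    }),
    similarity = map_dbl(candidates$members, function(m) {
      disease_similarity(m, reference, universe_size)
    })
  )
  rec <- arrange(rec, dplyr::desc(.data$similarity), .data$disease)
  eligible <- rec$overlap >= min_shared
  if (sum(eligible) < k) {
    warn(sprintf("Only %d of %d candidate diseases share >= %d genes; returning all eligible.",
                 sum(eligible), nrow(rec), min_shared))
  }
  rec$selected <- eligible & cumsum(eligible) <= k
  arrange(rec, dplyr::desc(.data$selected), dplyr::desc(.data$similarity), .data$disease)
}

#' Binary similar-disease target features
#'
#' One `{0,1}` column per selected disease: 1 if the protein is a target of
#' that disease, 0 otherwise.
#'
#' @param candidates Gene-set tibble holding the disease target sets.
#' @param selection Output of [select_similar_diseases()] (only rows with
#'   `selected == TRUE` contribute columns).
#' @param universe Integer vector of protein ids (row index of the output).
#' @return Tibble with `protein_id` and one `sim.<disease>` column per
#'   selected disease.
#' @export
similarity_features <- function(candidates, selection, universe) {
  universe <- sort(unique(as.integer(universe)))
  out <- tibble(protein_id = universe)
  for (d in selection$disease[selection$selected]) {
    m <- candidates$members[[match(d, candidates$name)]]
    out[[paste0("sim.", d)]] <- as.numeric(universe %in% m)
  }
  out
}

#' Disease-similarity feature block for a knowledge base
#'
#' Convenience wrapper: selects up to `k` similar diseases against the
#' pooled positive-control target set and emits their binary feature
#' columns.
#'
#' @param kb An `mcl_kb` with candidate similar-disease sets.
#' @param reference Reference gene set; defaults to the pooled
#'   positive-control targets (see [define_positive_controls()]).
#' @param k,min_shared Selection controls, as in [select_similar_diseases()].
#' @return List with `selection` (ranking table) and `features` (binary
#'   columns keyed by `protein_id`).
#' @export
score_similarity <- function(kb, reference = NULL, k = 15L, min_shared = 3L) {
  if (is.null(reference)) reference <- define_positive_controls(kb)
  sel <- select_similar_diseases(kb$similar_diseases, reference,
                                 universe_size = nrow(kb$proteins),
                                 k = k, min_shared = min_shared)
  feats <- similarity_features(kb$similar_diseases, sel, protein_universe(kb))
  list(selection = sel, features = feats)
}
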