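# Knowledge-based per-protein scores for one disorder: biomarker status,
# biomarker enrichment of the direct interaction neighborhood, accumulated
# pathway-map enrichment, consortium pathway membership counts, and the
# biomarker co-occurrence ratio on linear signaling chains.
#
# All enrichment p-values use the shared upper-tail hypergeometric kernel
# with the full protein universe as background, natural-log transformed and
# clamped so scores are always finite and non-negative.

P_FLOOR <- 1e-300

neglog <- function(p) pmax(-log(pmax(p, P_FLOOR)), 0)

disorder_row <- function(kb, disorder) {
  i <- match(disorder, kb$disorders$disorder)
  if (is.na(i)) abort(paste0("Unknown disorder: ", disorder))
  i
}

#' Biomarker indicator score
#'
#' 1 for proteins annotated as biomarkers of the disorder, 0 otherwise.
#'
#' @param kb An `mcl_kb`.
#' @param disorder Disorder name present in `kb$disorders`.
#' @return Tibble `protein_id`, `score` over the full universe.
#' @export
biomarker_score <- function(kb, disorder) {
  i <- disorder_row(kb, disorder)
  ids <- protein_universe(kb)
  tibble(protein_id = ids,
         score = as.numeric(ids %in% kb$disorders$biomarkers[[i]]))
}

#' Interaction-neighborhood biomarker enrichment
#'
#' For each protein with degree `d > 0`, tests its direct interaction
#' neighbors for over-representation of the disorder's biomarkers
#' (upper-tail hypergeometric against the full universe) and scores the
#' protein as the negative natural log of that p-value.  Isolated proteins
#' score 0.
#'
#' @inheritParams biomarker_score
#' @return Tibble `protein_id`, `score` (non-negative).
#' @export
interaction_inference <- function(kb, disorder) {
  i <- disorder_row(kb, disorder)
  biomarkers <- kb$disorders$biomarkers[[i]]
  if (!length(biomarkers)) abort("Disorder has no biomarkers.")
  graph <- build_graph(kb)
  ids <- as.integer(igraph::V(graph)$name)
  a <- adjacency_of(graph)
  deg <- as.integer(Matrix::rowSums(a))
  hits <- as.integer(a %*% (ids %in% biomarkers))
  n_univ <- length(ids)
  score <- numeric(length(ids))
  nz <- deg > 0
  p <- hypergeom_tail(hits[nz], deg[nz], length(biomarkers), n_univ)
  score[nz] <- neglog(p)
  out <- tibble(protein_id = ids, score = score)
  arrange(out, .data$protein_id)
}

#' Accumulated pathway-map enrichment score
#'
#' Each pathway map is tested for biomarker over-representation, yielding a
#' per-pathway score \eqn{s_P = -\ln p_P}; a protein's score is the sum of
#' \eqn{s_P} over the pathways containing it, so proteins sitting on many
#' biomarker-enriched maps accumulate evidence additively.
#'
#' @inheritParams biomarker_score
#' @return Tibble `protein_id`, `score` (non-negative).
#' @export
pathway_enrichment_score <- function(kb, disorder) {
  i <- disorder_row(kb, disorder)
  biomarkers <- kb$disorders$biomarkers[[i]]
  ids <- protein_universe(kb)
  n_univ <- length(ids)
  score <- setNames(numeric(n_univ), ids)
  pw <- kb$pathway_maps
  if (nrow(pw)) {
    sizes <- lengths(pw$members)
    hits <- map_int(pw$members, function(m) length(intersect(m, biomarkers)))
    s_p <- neglog(hypergeom_tail(hits, sizes, length(biomarkers), n_univ))
    for (j in seq_len(nrow(pw))) {
      key <- as.character(pw$members[[j]])
      score[key] <- score[key] + s_p[j]
    }
  }
  tibble(protein_id = ids, score = unname(score))
}

#' Consortium pathway membership count
#'
#' Disorder-independent count of curated consortium (disease-area) pathways
#' on which each protein appears.
#'
#' @param kb An `mcl_kb`.
#' @return Tibble `protein_id`, `score` (non-negative integer-valued).
#' @export
metaminer_count <- function(kb) {
  ids <- protein_universe(kb)
  counts <- table(factor(unlist(kb$metaminer_pathways$members), levels = ids))
  tibble(protein_id = ids, score = as.numeric(counts))
}

#' Linear-pathway biomarker co-occurrence ratio
#'
#' Fraction of the linear signaling chains containing the protein that also
#' contain at least one disorder biomarker.  Proteins on no chain score 0
#' (no chain evidence either way).
#'
#' @inheritParams biomarker_score
#' @return Tibble `protein_id`, `score` in `[0, 1]`.
#' @export
linear_pathway_score <- function(kb, disorder) {
  i <- disorder_row(kb, disorder)
  biomarkers <- kb$disorders$biomarkers[[i]]
  ids <- protein_universe(kb)
  on_chain <- setNames(numeric(length(ids)), ids)
  with_bm <- on_chain
  for (chain in kb$linear_pathways$chain) {
    key <- as.character(unique(chain))
    on_chain[key] <- on_chain[key] + 1
    if (any(chain %in% biomarkers)) with_bm[key] <- with_bm[key] + 1
  }
  tibble(protein_id = ids,
         score = unname(ifelse(on_chain > 0, with_bm / on_chain, 0)))
}

#' All knowledge-based scores, per disorder
#'
#' Computes the four disorder-specific knowledge scores for every annotated
#' disorder plus the global consortium membership count, in one wide table.
#'
#' @param kb An `mcl_kb`.
#' @return Tibble with `protein_id` and columns
#'   `<disorder>.biomarker`, `<disorder>.interaction`, `<disorder>.pathway`,
#'   `<disorder>.linear` for each disorder, plus `metaminer.count`.
#' @export
score_knowledge <- function(kb) {
  out <- tibble(protein_id = protein_universe(kb))
  for (d in kb$disorders$disorder) {
    out[[paste0(d, ".biomarker")]] <- biomarker_score(kb, d)$score
    out[[paste0(d, ".interaction")]] <- interaction_inference(kb, d)$score
    out[[paste0(d, ".pathway")]] <- pathway_enrichment_score(kb, d)$score
    out[[paste0(d, ".linear")]] <- linear_pathway_score(kb, d)$score
  }
  out[["metaminer.count"]] <- metaminer_count(kb)$score
  out
}
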