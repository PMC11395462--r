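# Exact hypergeometric over-representation statistics.  The upper-tail
# convention P(X >= r) is used throughout the package: it is the convention
# under which published worked examples of molecular-function enrichment
# reproduce exactly (including the r = n single-term tails, which admit a
# closed form checkable by hand).

#' Upper-tail hypergeometric probability
#'
#' Probability of drawing at least `r` annotated genes when `R` genes are
#' drawn without replacement from a universe of `N` genes of which `n` carry
#' the annotation:
#' \deqn{p = \sum_{x=r}^{\min(R,n)} \binom{n}{x}\binom{N-n}{R-x} / \binom{N}{R}}
#' Evaluated through [stats::phyper()], which works on log scale internally;
#' `log_p = TRUE` returns \eqn{\log p} directly and stays finite even where
#' the tail underflows double precision (large `N`, extreme `r`).
#'
#' @param r Observed hits in the query set (vectorized).
#' @param R Query-set size.
#' @param n Annotation (term) size in the universe.
#' @param N Universe size.
#' @param log_p Return the natural log of the tail probability.
#' @return Numeric vector of tail probabilities (or their logs).
#' @export
hypergeom_tail <- function(r, R, n, N, log_p = FALSE) {
  args <- vctrs_recycle(r = r, R = R, n = n, N = N)
  r <- args$r; R <- args$R; n <- args$n; N <- args$N
  if (any(r < 0 | R < 0 | n < 0 | N < 1)) abort("Counts must be non-negative (N >= 1).")
  if (any(r > pmin(R, n))) abort("`r` cannot exceed min(R, n).")
  if (any(R > N | n > N)) abort("`R` and `n` cannot exceed `N`.")
  p <- phyper(r - 1, n, N - n, R, lower.tail = FALSE, log.p = log_p)
  if (log_p) pmin(p, 0) else pmin(p, 1)
}

# minimal common-length recycling with informative failure
vctrs_recycle <- function(...) {
  args <- list(...)
  len <- max(lengths(args))
  bad <- lengths(args) != len & lengths(args) != 1L
  if (any(bad)) abort("Arguments must have length 1 or a common length.")
  map(args, rep_len, len)
}

#' Hypergeometric term enrichment of a query gene set
#'
#' Tests each annotation term for over-representation in the query set.
#' Following the convention of molecular-function enrichment tables, the
#' universe is the set of genes carrying at least one annotation, and the
#' query is intersected with it before testing.
#'
#' @param query_set Integer vector of query gene ids.
#' @param annotation_sets Gene-set tibble (see [gene_sets()]) of flat
#'   annotation terms.
#' @param universe Integer vector of universe gene ids; defaults to the
#'   union of all annotation sets (genes with >= 1 annotation).
#' @param bh Add a Benjamini-Hochberg adjusted column `p_adj` (off by
#'   default; published tables print raw p).
#' @return Tibble with one row per term with at least one hit, columns
#'   `term`, `r`, `R`, `n`, `N`, `p`, sorted by ascending `p` with ties
#'   broken by term name.
#' @export
enrich_terms <- function(query_set, annotation_sets, universe = NULL, bh = FALSE) {
  if (is.null(universe)) universe <- unique(unlist(annotation_sets$members))
  universe <- unique(as.integer(universe))
  if (!length(universe)) abort("Annotation universe is empty.")
  query <- intersect(unique(as.integer(query_set)), universe)
  res <- tibble(
    term = annotation_sets$name,
    r = map_int(annotation_sets$members, function(m) {
      length(intersect(intersect(m, universe), query))
    }),
    R = length(query),
    n = map_int(annotation_sets$members, function(m) length(intersect(m, universe))),
    N = length(universe)
  )
  res <- filter(res, .data$r > 0)
  res$p <- hypergeom_tail(res$r, res$R, res$n, res$N)
  if (bh) res$p_adj <- stats::p.adjust(res$p, method = "BH")
  arrange(res, .data$p, .data$term)
}
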