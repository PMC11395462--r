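# Topology-based guilt-by-association scores over the undirected simple
# interactome.  Two global diffusion methods (degree-normalized propagation
# and random walk with restart) and two local ones (interconnectivity and
# one-step neighborhood smoothing).  Seeds are disorder biomarkers; by
# default the pooled biomarkers of all disorders in the knowledge base.

adjacency_of <- function(graph) {
  igraph::as_adjacency_matrix(graph, sparse = TRUE)
}

seed_indicator <- function(graph, seeds) {
  nodes <- igraph::V(graph)$name
  seeds <- as.character(seeds)
  missing <- setdiff(seeds, nodes)
  if (length(missing)) {
    abort(paste0("Seed node(s) not in graph: ", paste(head(missing, 5), collapse = ", ")))
  }
  as.numeric(nodes %in% seeds)
}

score_tibble <- function(graph, score) {
  tibble(protein_id = as.integer(igraph::V(graph)$name), score = as.numeric(score))
}

#' Network propagation of seed flow
#'
#' Diffuses unit flow injected at the seed nodes over the degree-normalized
#' interactome until equilibrium.  The update is
#' \deqn{F_t = \alpha W' F_{t-1} + (1-\alpha) Y}
#' where `Y` indicates the seeds and `W'` is the symmetric degree
#' normalization \eqn{w'_{ij} = a_{ij}/\sqrt{\deg i \cdot \deg j}}, which
#' compensates for hub bias.  The converged flow measures global proximity
#' of every protein to the seed set.
#'
#' @param graph Undirected simple [igraph::igraph] with protein-id names.
#' @param seeds Protein ids to inject flow at.
#' @param alpha Diffusion weight in `[0, 1)`; default 0.8.
#' @param tol Max-norm convergence threshold on the flow change.
#' @param max_iter Iteration cap; exceeded -> error carrying the count.
#' @return Tibble `protein_id`, `score` (non-negative flow).
#' @export
network_propagation <- function(graph, seeds, alpha = 0.8,
                                tol = 1e-8, max_iter = 1000L) {
  stopifnot(alpha >= 0, alpha < 1, tol > 0)
  y <- seed_indicator(graph, seeds)
  if (!any(y > 0)) {
    warn("Empty seed set: propagation flow is identically zero.")
    return(score_tibble(graph, numeric(length(y))))
  }
  a <- adjacency_of(graph)
  d <- Matrix::rowSums(a)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  w <- Diagonal(x = inv_sqrt) %*% a %*% Diagonal(x = inv_sqrt)
  f <- y
  for (it in seq_len(max_iter)) {
    f_new <- as.numeric(alpha * (w %*% f)) + (1 - alpha) * y
    if (max(abs(f_new - f)) < tol) return(score_tibble(graph, f_new))
    f <- f_new
  }
  abort(sprintf("Network propagation did not converge in %d iterations.", max_iter))
}

#' Random walk with restart from seed nodes
#'
#' Stationary visiting probability of a walker that moves to a uniformly
#' random neighbor each step and teleports back to the seed distribution
#' with probability `restart`:
#' \deqn{p_t = (1-r) W p_{t-1} + r\, p^0}
#' `W` is the column-stochastic transition matrix \eqn{a_{ij}/\deg j};
#' an isolated node's column is made self-absorbing to preserve
#' stochasticity.  `p^0` is uniform over the seeds.  The converged vector
#' is a probability distribution (sums to one).
#'
#' @inheritParams network_propagation
#' @param restart Restart probability in `(0, 1]`; default 0.75.
#' @return Tibble `protein_id`, `score` (visiting probability).
#' @export
random_walk_restart <- function(graph, seeds, restart = 0.75,
                                tol = 1e-8, max_iter = 1000L) {
  stopifnot(restart > 0, restart <= 1, tol > 0)
  y <- seed_indicator(graph, seeds)
  if (!any(y > 0)) {
    warn("Empty seed set: restart distribution undefined, returning zeros.")
    return(score_tibble(graph, numeric(length(y))))
  }
  p0 <- y / sum(y)
  a <- adjacency_of(graph)
  d <- Matrix::colSums(a)
  w <- a %*% Diagonal(x = ifelse(d > 0, 1 / d, 0))
  iso <- which(d == 0)
  if (length(iso)) w <- w + Matrix::sparseMatrix(i = iso, j = iso, x = 1, dims = dim(w))
  p <- p0
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric((1 - restart) * (w %*% p)) + restart * p0
    if (max(abs(p_new - p)) < tol) return(score_tibble(graph, p_new))
    p <- p_new
  }
  abort(sprintf("Random walk with restart did not converge in %d iterations.", max_iter))
}

#' Interconnectivity score to a seed set
#'
#' Local degree-corrected connectivity between a protein and each seed,
#' averaged over the seed set:
#' \deqn{ICN(i,j) = \frac{2\,e(i,j) + n(i,j)}{\sqrt{\deg i \cdot \deg j}},
#'   \qquad Score(i) = \frac{1}{|S|} \sum_{j \in S} ICN(i,j)}
#' with `e(i,j)` the direct-edge indicator and `n(i,j)` the shared-neighbor
#' count.  Pairs involving a degree-zero node contribute 0.
#'
#' @inheritParams network_propagation
#' @return Tibble `protein_id`, `score`.
#' @export
interconnectivity_score <- function(graph, seeds) {
  y <- seed_indicator(graph, seeds)
  if (!any(y > 0)) {
    warn("Empty seed set: interconnectivity is identically zero.")
    return(score_tibble(graph, numeric(length(y))))
  }
  a <- adjacency_of(graph)
  d <- Matrix::rowSums(a)
  idx <- which(y > 0)
  # columns of (2A + A^2) restricted to seeds; A^2[i,j] = shared neighbors
  numer <- 2 * a[, idx, drop = FALSE] + a %*% a[, idx, drop = FALSE]
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  icn <- Diagonal(x = inv_sqrt) %*% numer %*% Diagonal(x = inv_sqrt[idx])
  score_tibble(graph, Matrix::rowSums(icn) / length(idx))
}

#' Neighborhood smoothing of a node-level signal
#'
#' One-step convex smoothing of a per-node level (1 on biomarkers, 0
#' elsewhere in the default use) over direct neighbors:
#' \deqn{FC'_i = \alpha\, FC_i + (1-\alpha)\, \frac{1}{N_i}\sum_{j \sim i} FC_j}
#' A node without neighbors keeps only its own term \eqn{\alpha FC_i}.
#'
#' @inheritParams network_propagation
#' @param seed_levels Either protein ids (interpreted as level 1, rest 0) or
#'   a full numeric vector named by protein id.
#' @param alpha Self weight in `[0, 1]`; default 0.5.
#' @return Tibble `protein_id`, `score`.
#' @export
neighborhood_score <- function(graph, seed_levels, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  nodes <- igraph::V(graph)$name
  if (!is.null(names(seed_levels))) {
    fc <- numeric(length(nodes))
    pos <- match(names(seed_levels), nodes)
    if (anyNA(pos)) abort("Named levels refer to nodes absent from the graph.")
    fc[pos] <- as.numeric(seed_levels)
  } else {
    fc <- seed_indicator(graph, seed_levels)
  }
  a <- adjacency_of(graph)
  d <- Matrix::rowSums(a)
  nbr_mean <- ifelse(d > 0, as.numeric(a %*% fc) / d, 0)
  score_tibble(graph, alpha * fc + (1 - alpha) * nbr_mean)
}

#' All four network scores for a knowledge base
#'
#' Runs propagation, random walk with restart, interconnectivity and
#' neighborhood smoothing with the given seed set (default: the pooled
#' biomarkers of all annotated disorders).
#'
#' @param kb An `mcl_kb`.
#' @param seeds Seed protein ids; default pools all disorder biomarkers.
#' @param alpha Propagation diffusion weight.
#' @param restart RWR restart probability.
#' @param alpha_smooth Neighborhood self weight.
#' @param tol,max_iter Convergence controls for the iterative methods.
#' @return Tibble `protein_id`, `net.propagation`, `net.rwr`, `net.icn`,
#'   `net.neighborhood`.
#' @export
score_network <- function(kb, seeds = NULL, alpha = 0.8, restart = 0.75,
                          alpha_smooth = 0.5, tol = 1e-8, max_iter = 1000L) {
  graph <- build_graph(kb)
  if (is.null(seeds)) seeds <- pooled_biomarkers(kb)
  out <- network_propagation(graph, seeds, alpha = alpha, tol = tol, max_iter = max_iter)
  out <- rename(out, net.propagation = "score")
  out$net.rwr <- random_walk_restart(graph, seeds, restart = restart,
                                     tol = tol, max_iter = max_iter)$score
  out$net.icn <- interconnectivity_score(graph, seeds)$score
  out$net.neighborhood <- neighborhood_score(graph, seeds, alpha = alpha_smooth)$score
  out
}

#' Pooled biomarkers across all annotated disorders
#' @param kb An `mcl_kb`.
#' @return Sorted integer vector of biomarker protein ids.
#' @export
pooled_biomarkers <- function(kb) {
  sort(unique(unlist(kb$disorders$biomarkers)))
}
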