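# Direct linear-system solves used as independent oracles for the two
# iterative diffusion methods.
solve_propagation <- function(graph, seeds, alpha) {
  a <- as.matrix(igraph::as_adjacency_matrix(graph))
  d <- rowSums(a)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  w <- diag(inv_sqrt) %*% a %*% diag(inv_sqrt)
  y <- as.numeric(igraph::V(graph)$name %in% as.character(seeds))
  as.numeric((1 - alpha) * solve(diag(nrow(a)) - alpha * w, y))
}

solve_rwr <- function(graph, seeds, r) {
  a <- as.matrix(igraph::as_adjacency_matrix(graph))
  d <- colSums(a)
  w <- a %*% diag(ifelse(d > 0, 1 / d, 0))
  iso <- which(d == 0)
  if (length(iso)) w[cbind(iso, iso)] <- 1
  y <- as.numeric(igraph::V(graph)$name %in% as.character(seeds))
  p0 <- y / sum(y)
  as.numeric(r * solve(diag(nrow(a)) - (1 - r) * w, p0))
}

test_that("propagation matches the closed-form linear solve on a path graph", {
  g <- igraph::make_ring(5, circular = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(1:5))
  f <- network_propagation(g, seeds = 1, alpha = 0.8)
  expect_equal(f$score, solve_propagation(g, 1, 0.8), tolerance = 1e-6)
  expect_true(all(f$score >= 0))
})

test_that("iterative diffusion equals direct solves on random graphs", {
  set.seed(7)
  for (trial in 1:50) {
    n <- sample(20:200, 1)
    g <- random_test_graph(n, p = 2 / n)
    seeds <- sample(n, sample(1:5, 1))
    f <- network_propagation(g, seeds, alpha = 0.8, tol = 1e-10)
    expect_lt(max(abs(f$score - solve_propagation(g, seeds, 0.8))), 1e-6)
    p <- random_walk_restart(g, seeds, restart = 0.75, tol = 1e-12)
    expect_lt(max(abs(p$score - solve_rwr(g, seeds, 0.75))), 1e-6)
  }
})

test_that("diffusion limit cases hold exactly", {
  g <- random_test_graph(30, p = 0.1)
  seeds <- c(1, 5, 9)
  y <- as.numeric(1:30 %in% seeds)
  # alpha = 0: propagation returns the prior indicator
  f0 <- network_propagation(g, seeds, alpha = 0)
  expect_equal(f0$score, y)
  # restart = 1: walker never leaves the seed distribution
  p1 <- random_walk_restart(g, seeds, restart = 1)
  expect_equal(p1$score, y / sum(y))
  # empty seed set: zero vector with a warning
  expect_warning(fz <- network_propagation(g, integer(0)), "Empty seed")
  expect_equal(fz$score, rep(0, 30))
})

test_that("restart distribution conserves probability mass", {
  set.seed(3)
  for (trial in 1:5) {
    g <- random_test_graph(80, p = 0.04)  # likely has isolated nodes
    p <- random_walk_restart(g, seeds = sample(80, 3), tol = 1e-12)
    expect_equal(sum(p$score), 1, tolerance = 1e-10)
  }
})

test_that("propagation spreads to everything connected to a seed", {
  g <- igraph::make_ring(6, circular = FALSE)
  g <- igraph::add_vertices(g, 2)  # two isolated nodes
  g <- igraph::set_vertex_attr(g, "name", value = as.character(1:8))
  f <- network_propagation(g, seeds = 1, alpha = 0.8)
  expect_true(all(f$score[1:6] > 0))
  expect_equal(f$score[7:8], c(0, 0))
})

test_that("interconnectivity matches hand enumeration on a triangle", {
  g <- igraph::make_full_graph(3)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(1:3))
  s <- interconnectivity_score(g, seeds = 2)
  # ICN(1,2) = (2*1 + 1) / sqrt(2*2) = 1.5
  expect_equal(s$score[s$protein_id == 1], 1.5)
  expect_equal(s$score[s$protein_id == 3], 1.5)
})

test_that("interconnectivity equals brute-force shared-neighbor enumeration", {
  icn_pair <- function(a, i, j) {
    di <- sum(a[i, ]); dj <- sum(a[j, ])
    if (di == 0 || dj == 0) return(0)
    shared <- sum(a[i, ] & a[j, ])
    (2 * a[i, j] + shared) / sqrt(di * dj)
  }
  set.seed(11)
  for (trial in 1:10) {
    n <- sample(10:50, 1)
    g <- random_test_graph(n, p = 0.15)
    a <- as.matrix(igraph::as_adjacency_matrix(g))
    seeds <- sample(n, 3)
    s <- interconnectivity_score(g, seeds)
    expected <- vapply(seq_len(n), function(i) {
      mean(vapply(seeds, function(j) icn_pair(a, i, j), numeric(1)))
    }, numeric(1))
    expect_equal(s$score, expected, tolerance = 1e-12)
    # symmetry of the pairwise score
    for (k in 1:10) {
      ij <- sample(n, 2)
      expect_equal(icn_pair(a, ij[1], ij[2]), icn_pair(a, ij[2], ij[1]))
    }
  }
})

test_that("neighborhood smoothing is a convex one-step average", {
  # star: center 1 with leaves 2..5; levels 1 on leaves 2 and 3
  g <- igraph::make_star(5, mode = "undirected", center = 1)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(1:5))
  s <- neighborhood_score(g, seed_levels = c(2, 3), alpha = 0.5)
  expect_equal(s$score[s$protein_id == 1], 0.25)  # 0.5*0 + 0.5*(2/4)
  expect_equal(s$score[s$protein_id == 2], 0.5)   # own level 1, neighbor 0
  # constant field is a fixed point
  levels <- stats::setNames(rep(0.7, 5), as.character(1:5))
  s2 <- neighborhood_score(g, seed_levels = levels, alpha = 0.5)
  expect_equal(s2$score, rep(0.7, 5))
  # degree-0 node keeps only its own weighted level
  g2 <- igraph::add_vertices(g, 1)
  g2 <- igraph::set_vertex_attr(g2, "name", value = as.character(1:6))
  s3 <- neighborhood_score(g2, seed_levels = c(6), alpha = 0.5)
  expect_equal(s3$score[s3$protein_id == 6], 0.5)
})

test_that("all four scorers are permutation-equivariant", {
  set.seed(23)
  g <- random_test_graph(40, p = 0.1)
  seeds <- c(3, 17, 25)
  perm <- sample(40)
  # relabel vertex names by the permutation
  g2 <- igraph::set_vertex_attr(g, "name", value = as.character(perm))
  seeds2 <- perm[seeds]
  for (fn in list(
    function(g, s) network_propagation(g, s, tol = 1e-12),
    function(g, s) random_walk_restart(g, s, tol = 1e-12),
    interconnectivity_score,
    function(g, s) neighborhood_score(g, s)
  )) {
    a <- fn(g, seeds)
    b <- fn(g2, seeds2)
    expect_equal(b$score[match(perm, b$protein_id)], a$score, tolerance = 1e-9)
  }
})

test_that("score_network seeds with pooled biomarkers by default", {
  kb <- tiny_kb()
  ns <- score_network(kb)
  expect_named(ns, c("protein_id", "net.propagation", "net.rwr",
                     "net.icn", "net.neighborhood"))
  manual <- network_propagation(build_graph(kb), pooled_biomarkers(kb))
  expect_equal(ns$net.propagation, manual$score)
})
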