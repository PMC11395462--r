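test_that("biomarker indicator marks exactly the annotated biomarkers", {
  kb <- tiny_kb()
  s <- biomarker_score(kb, "dA")
  expect_equal(s$score[s$protein_id %in% c(1, 3)], c(1, 1))
  expect_equal(sum(s$score), 2)
  expect_true(all(s$score %in% c(0, 1)))
  expect_error(biomarker_score(kb, "nope"), "Unknown disorder")
})

test_that("interaction-neighborhood enrichment matches the hand-computed tail", {
  # protein 1 has 4 neighbors of which 2 are biomarkers; 10 biomarkers in a
  # universe of 100.  Direct pmf summation gives P(X >= 2 | N=100, K=10, n=4)
  # = 0.04877, so the score is -ln p ~ 3.021.
  proteins <- tibble::tibble(id = 1:100, symbol = paste0("P", 1:100))
  interactions <- tibble::tibble(
    source = c(1L, 1L, 1L, 1L),
    target = c(2L, 3L, 4L, 5L),
    effect = "activation", mechanism = "binding"
  )
  disorders <- tibble::tibble(
    disorder = "dX",
    biomarkers = list(c(2L, 3L, 91:98)),  # neighbors 2,3 plus 8 elsewhere
    targets = list(integer(0)),
    status = list(stats::setNames(character(0), character(0)))
  )
  kb <- knowledge_base(proteins, interactions, disorders = disorders)
  s <- interaction_inference(kb, "dX")
  expected <- -log(oracle_tail(2, 4, 10, 100))
  expect_equal(s$score[s$protein_id == 1], expected, tolerance = 1e-12)
  expect_equal(round(s$score[s$protein_id == 1], 3), 3.021)
  # isolated proteins score zero
  expect_equal(s$score[s$protein_id == 50], 0)
})

test_that("interaction enrichment agrees with brute-force oracle on random graphs", {
  set.seed(42)
  for (trial in 1:5) {
    n <- 40
    g <- random_test_graph(n, p = 0.12)
    el <- igraph::as_edgelist(g)
    proteins <- tibble::tibble(id = 1:n, symbol = paste0("P", 1:n))
    interactions <- tibble::tibble(
      source = pmin(as.integer(el[, 1]), as.integer(el[, 2])),
      target = pmax(as.integer(el[, 1]), as.integer(el[, 2])),
      effect = "activation", mechanism = "binding"
    )
    interactions <- dplyr::distinct(interactions, source, target, .keep_all = TRUE)
    bm <- sort(sample(n, 6))
    disorders <- tibble::tibble(
      disorder = "dX", biomarkers = list(bm), targets = list(integer(0)),
      status = list(stats::setNames(character(0), character(0)))
    )
    kb <- knowledge_base(proteins, interactions, disorders = disorders)
    s <- interaction_inference(kb, "dX")
    gk <- build_graph(kb)
    for (i in sample(n, 10)) {
      nbrs <- as.integer(igraph::neighbors(gk, as.character(i))$name)
      expected <- if (length(nbrs) == 0) 0 else {
        max(-log(oracle_tail(sum(nbrs %in% bm), length(nbrs), 6, n)), 0)
      }
      expect_equal(s$score[s$protein_id == i], expected, tolerance = 1e-9)
    }
  }
})

test_that("more biomarker neighbors at equal degree means a larger score", {
  # star centers with degree 4 and 0..4 biomarker neighbors
  proteins <- tibble::tibble(id = 1:60, symbol = paste0("P", 1:60))
  centers <- 1:5
  edges <- purrr::map(centers, function(c0) {
    nb <- 5 + (c0 - 1) * 4 + 1:4
    tibble::tibble(source = c0, target = nb)
  })
  interactions <- dplyr::bind_rows(edges)
  interactions$source <- as.integer(interactions$source)
  interactions$target <- as.integer(interactions$target)
  interactions$effect <- "activation"; interactions$mechanism <- "binding"
  # biomarkers: k of center c0's neighbors are biomarkers, k = c0 - 1
  bm <- unlist(purrr::map(centers, function(c0) {
    nb <- 5 + (c0 - 1) * 4 + 1:4
    head(nb, c0 - 1)
  }))
  disorders <- tibble::tibble(
    disorder = "dX", biomarkers = list(sort(as.integer(bm))),
    targets = list(integer(0)),
    status = list(stats::setNames(character(0), character(0)))
  )
  kb <- knowledge_base(proteins, interactions, disorders = disorders)
  s <- interaction_inference(kb, "dX")
  center_scores <- s$score[match(centers, s$protein_id)]
  expect_true(all(diff(center_scores) > 0))
  expect_true(all(s$score >= 0))
})

test_that("pathway enrichment is additive over containing pathways", {
  # one 5-member pathway holding 3 of 10 biomarkers in a universe of 100
  proteins <- tibble::tibble(id = 1:100, symbol = paste0("P", 1:100))
  pw <- gene_sets(c("p1", "p2"), list(1:5, c(1L, 20L, 21L)))
  disorders <- tibble::tibble(
    disorder = "dX", biomarkers = list(c(1:3, 51:57)),
    targets = list(integer(0)),
    status = list(stats::setNames(character(0), character(0)))
  )
  kb <- knowledge_base(proteins, pathway_maps = pw, disorders = disorders)
  s <- pathway_enrichment_score(kb, "dX")
  s1 <- -log(oracle_tail(3, 5, 10, 100))   # p1: 3 biomarkers of 5 members
  s2 <- -log(oracle_tail(1, 3, 10, 100))   # p2: 1 biomarker of 3 members
  # members only on p1 get s1; protein 1 is on both and accumulates
  expect_equal(s$score[s$protein_id == 2], s1, tolerance = 1e-12)
  expect_equal(s$score[s$protein_id == 1], s1 + s2, tolerance = 1e-12)
  expect_equal(s$score[s$protein_id == 99], 0)
})

test_that("consortium membership counting satisfies the double-counting identity", {
  kb <- tiny_kb()
  s <- metaminer_count(kb)
  expect_equal(s$score[s$protein_id == 2], 3)  # on all three consortium maps
  expect_equal(s$score[s$protein_id == 10], 0)
  expect_equal(sum(s$score), sum(lengths(kb$metaminer_pathways$members)))
})

test_that("linear-pathway ratio counts chains with biomarkers", {
  kb <- tiny_kb()  # dA biomarkers {1,3}; chains: {1,2,3}, {4,5,6}, {2,4}, {7,8}
  s <- linear_pathway_score(kb, "dA")
  expect_equal(s$score[s$protein_id == 2], 0.5)   # on c1 (has biomarker) and c3 (none)
  expect_equal(s$score[s$protein_id == 1], 1.0)   # only on c1
  expect_equal(s$score[s$protein_id == 5], 0.0)   # only on c2, no biomarkers
  expect_equal(s$score[s$protein_id == 10], 0.0)  # on no chain: no evidence
  expect_true(all(s$score >= 0 & s$score <= 1))
})

test_that("the knowledge score table has one block per disorder plus the count", {
  kb <- tiny_kb()
  ks <- score_knowledge(kb)
  expect_equal(ncol(ks), 1 + 2 * 4 + 1)
  expect_true(all(c("dA.biomarker", "dB.linear", "metaminer.count") %in% names(ks)))
  expect_equal(ks$protein_id, 1:10)
})
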