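test_that("feature assembly lays out the expected column blocks", {
  gen <- generate_kb(small_synth_config())
  feats <- build_feature_matrix(gen$kb)
  d <- small_synth_config()$n_disorders
  # 4 knowledge scores per disorder + global count + 4 network + 8 similarity
  expect_equal(ncol(feats) - 1, d * 4 + 1 + 4 + 8)
  prov <- attr(feats, "provenance")
  expect_equal(nrow(prov), ncol(feats) - 1)
  expect_setequal(unique(prov$module), c("knowledge", "network", "similarity"))
  expect_false(anyNA(as.matrix(feats[-1])))
  expect_false(anyDuplicated(names(feats)) > 0)
})

test_that("feature assembly rejects blocks from a different universe", {
  gen <- generate_kb(small_synth_config())
  wrong <- tibble::tibble(protein_id = 1:5, net.propagation = 0)
  expect_error(build_feature_matrix(gen$kb, network = wrong), "network")
})

test_that("negative sampling is disjoint from positives and sized by the ratio", {
  set.seed(1)
  universe <- 1:1000
  positives <- sample(universe, 50)
  negs <- sample_negatives(universe, positives, ratio = 10)
  expect_length(negs, 500)
  expect_length(intersect(negs, positives), 0)
  expect_length(unique(negs), 500)
  negs2 <- sample_negatives(universe, positives, ratio = 10)
  expect_false(identical(sort(negs), sort(negs2)))  # fresh draw each call
  expect_error(sample_negatives(1:100, 1:50, 10), "only 50")
})

test_that("recursive elimination keeps a perfectly separating feature", {
  set.seed(13)
  n <- 220
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, c("signal", paste0("noise", 1:9))))
  y <- as.numeric(x[, "signal"] > quantile(x[, "signal"], 0.8))
  x <- scale(x)
  rfe <- rfe_inner_loop(x, y, cv_config(rng_seed = 2))
  expect_true("signal" %in% rfe$selected)
  # curve starts at the full feature set and ends at pls_components
  expect_equal(rfe$curve$n_features[1], 10)
  expect_equal(min(rfe$curve$n_features), 2)
  expect_equal(nrow(rfe$curve), 9)  # one elimination step per feature dropped
  # error at the selected set is the curve minimum
  expect_equal(min(rfe$curve$error),
               rfe$curve$error[rfe$curve$n_features == length(rfe$selected)])
})

test_that("nested CV ranks a deterministic label construct perfectly", {
  set.seed(4)
  n <- 800
  feats <- tibble::tibble(
    protein_id = 1:n,
    driver = rnorm(n),
    noise1 = rnorm(n),
    noise2 = rnorm(n)
  )
  positives <- feats$protein_id[feats$driver > quantile(feats$driver, 0.95)]
  # labels are a threshold of the driver; give the threshold a margin so the
  # construct is separable with room to spare
  feats$driver[feats$protein_id %in% positives] <-
    feats$driver[feats$protein_id %in% positives] + 3
  res <- nested_cv_prioritize(feats, positives,
                              cv_config(repeats = 2, rng_seed = 5))
  expect_equal(roc_auc(res$scores, positives)$auc, 1.0)
  td <- tidy(res)
  expect_true(all(td$is_positive[seq_along(positives)]))
  expect_true(all(res$scores$final_score >= 1 &
                    res$scores$final_score <= n))
})

test_that("selection counts are bounded by repeats times outer folds", {
  gen <- generate_kb(small_synth_config())
  feats <- build_feature_matrix(gen$kb)
  res <- nested_cv_prioritize(feats, gen$truth$planted_targets,
                              cv_config(repeats = 2, rng_seed = 3))
  expect_true(all(res$selection_counts$count >= 0))
  expect_true(all(res$selection_counts$count <= 2 * 5))
  expect_true(any(res$selection_counts$count > 0))
})

test_that("identical seeds give identical prioritizations, different seeds differ", {
  set.seed(77)
  n <- 300
  feats <- tibble::tibble(
    protein_id = 1:n,
    a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n)
  )
  positives <- sample(n, 20)
  r1 <- nested_cv_prioritize(feats, positives, cv_config(repeats = 2, rng_seed = 9))
  r2 <- nested_cv_prioritize(feats, positives, cv_config(repeats = 2, rng_seed = 9))
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$selection_counts, r2$selection_counts)
  expect_identical(r1$rank_matrix, r2$rank_matrix)
  r3 <- nested_cv_prioritize(feats, positives, cv_config(repeats = 2, rng_seed = 10))
  expect_false(identical(r1$scores, r3$scores))
})

test_that("constant feature columns are dropped with a warning", {
  feats <- tibble::tibble(
    protein_id = 1:300, flat = 1, a = rnorm(300), b = rnorm(300)
  )
  expect_warning(
    res <- nested_cv_prioritize(feats, 1:10, cv_config(repeats = 1, rng_seed = 1)),
    "flat"
  )
  expect_false("flat" %in% res$selection_counts$feature)
})

test_that("tidy and glance summarize a prioritization", {
  set.seed(21)
  feats <- tibble::tibble(protein_id = 1:500, a = rnorm(500), b = rnorm(500),
                          c = rnorm(500))
  positives <- which(feats$a > 1.6)
  res <- nested_cv_prioritize(feats, positives, cv_config(repeats = 2, rng_seed = 1))
  td <- tidy(res)
  expect_equal(nrow(td), 500)
  expect_equal(td$rank, 1:500)
  expect_true(!is.unsorted(td$final_score))
  gl <- glance(res)
  expect_equal(gl$n_proteins, 500)
  expect_equal(gl$n_positives, length(positives))
  expect_true(gl$recovery_auc > 0.5)
  expect_s3_class(autoplot(res), "ggplot")
})
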