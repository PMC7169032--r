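test_that("roc_auc matches hand-enumerated pair counts", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  # pairs (0.8 vs 0.6, 0.2), (0.4 vs 0.6, 0.2) -> 1, 1, 0, 1 -> 3/4
  expect_equal(roc_auc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("roc_auc equals the all-pairs oracle and is monotone-invariant", {
  withr::with_seed(31, {
    for (i in 1:50) {
      n <- sample(4:50, 1)
      labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
      scores <- sample(seq(0, 1, 0.05), n, replace = TRUE) # forces ties
      expect_identical(roc_auc(scores, labels), oracle_auc(scores, labels))
      expect_equal(roc_auc(exp(scores), labels), roc_auc(scores, labels))
      expect_equal(roc_auc(3 * scores + 2, labels), roc_auc(scores, labels))
    }
  })
})

test_that("AUC quality bands use the standard half-open intervals", {
  expect_equal(auc_quality_label(0.815), "good")
  expect_equal(auc_quality_label(0.337), "worse_than_random")
  expect_equal(auc_quality_label(0.90), "excellent")
  expect_equal(auc_quality_label(0.7), "fair")
  expect_equal(auc_quality_label(0.65), "poor")
  expect_equal(auc_quality_label(0.55), "fail")
  expect_error(auc_quality_label(1.2), "\\[0, 1\\]")
})

test_that("bootstrap CI is seeded, stratified, and NA on tiny strata", {
  withr::with_seed(41, {
    scores <- c(runif(40, 0.6, 1), runif(60, 0, 0.4))
    labels <- rep(1:0, c(40, 60))
  })
  ci1 <- bootstrap_ci(scores, labels, n_replicates = 500, seed = 11)
  ci2 <- bootstrap_ci(scores, labels, n_replicates = 500, seed = 11)
  expect_identical(ci1, ci2)
  # perfect separation: no resample can create an inversion
  expect_equal(unname(ci1), c(1, 1))
  # a single positive gives the NA marker, not an error
  expect_true(all(is.na(bootstrap_ci(c(0.9, runif(20)),
                                     c(1, rep(0, 20)), seed = 1))))
  # interval covers the point estimate on noisy data
  withr::with_seed(43, {
    s <- c(rnorm(30, 1), rnorm(50, 0))
    l <- rep(1:0, c(30, 50))
  })
  auc <- roc_auc(s, l)
  ci <- bootstrap_ci(s, l, n_replicates = 500, seed = 3)
  expect_lt(ci[["ci_low"]], auc)
  expect_gt(ci[["ci_high"]], auc)
})

test_that("the cut-off sweep maximizes mean sensitivity/specificity", {
  res <- optimal_cutoff(c(0.9, 0.1), c(1, 0))
  expect_equal(res$cutoff, 0.11) # smallest grid point above the negative
  expect_equal(res$max_metric, 1)
  res2 <- optimal_cutoff(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(res2$max_metric, 1)
  # label permutation: metric near 1/2 on average
  withr::with_seed(47, {
    maxima <- replicate(100, {
      s <- runif(60)
      optimal_cutoff(s, sample(rep(1:0, c(20, 40))))$max_metric
    })
  })
  expect_lt(mean(maxima), 0.72) # max over the grid inflates slightly above 0.5
  expect_gt(mean(maxima), 0.5)
  expect_equal(nrow(res$sweep), 101)
})

test_that("ranking ties are broken deterministically by seed", {
  scores <- c(0.9, 0.5, 0.5, 0.5, 0.1)
  ids <- paste0("P", 1:5)
  r1 <- rank_candidates(ids, scores, c(0, 1, 0, 0, 1), tie_seed = 5)
  r2 <- rank_candidates(ids, scores, c(0, 1, 0, 0, 1), tie_seed = 5)
  expect_identical(r1, r2)
  expect_equal(r1$person_id[1], "P1")
  expect_equal(r1$person_id[5], "P5")
  expect_true(all(diff(r1$final_scaled) <= 0))
  expect_setequal(r1$person_id, ids)
})

test_that("P@k, MAP and MRR match their definitions", {
  rel <- c(0, 1, 0, 1, 0, rep(0, 15))
  expect_equal(precision_at_k(rel, 5), 0.4)
  expect_equal(precision_at_k(rel, 10), 0.2)
  expect_equal(precision_at_k(rep(1, 5), 5), 1)
  expect_equal(precision_at_k(rep(0, 10), 10), 0)
  expect_error(precision_at_k(c(1, 0), 5), "shorter")

  # relevant at ranks 1 and 3 -> (1 + 2/3) / 2
  expect_equal(average_precision(c(1, 0, 1, 0, 0)), (1 + 2 / 3) / 2)
  expect_equal(average_precision(c(1, 1, 1, 0)), 1)
  expect_equal(average_precision(c(rep(0, 9), 1)), 0.1)
  expect_error(average_precision(rep(0, 5)), "no relevant")

  expect_equal(reciprocal_rank(c(0, 0, 0, 1)), 0.25)
  expect_equal(reciprocal_rank(c(1, 0)), 1)
  rel2 <- integer(12); rel2[c(10, 2, 7)] <- 1L
  expect_equal(reciprocal_rank(rel2), 0.5)
})

test_that("reference bounds: closed-form upper, seeded random lower", {
  b7 <- reference_bounds(7, 1000, seed = 2)
  expect_equal(b7$upper, list(p5 = 1, p10 = 0.7, map = 1, mrr = 1))
  expect_equal(reference_bounds(2, 100)$upper$p5, 0.4)
  # an ideal list attains the upper reference exactly
  ideal <- c(rep(1, 7), rep(0, 993))
  expect_equal(average_precision(ideal), 1)
  expect_equal(reciprocal_rank(ideal), 1)
  expect_equal(precision_at_k(ideal, 5), b7$upper$p5)
  # determinism of the random lower reference
  expect_identical(reference_bounds(7, 1000, seed = 2), b7)
  # metric <= upper for random instances
  withr::with_seed(53, {
    for (i in 1:20) {
      n <- sample(20:100, 1)
      rel <- integer(n); rel[sample(n, sample(1:5, 1))] <- 1L
      expect_lte(average_precision(rel), 1)
      expect_lte(precision_at_k(rel, 10), min(sum(rel), 10) / 10)
      expect_lte(reciprocal_rank(rel), 1)
    }
  })
})

test_that("top-k overlap counts database-identified persons in the head", {
  flags <- c(rep(1, 33), rep(0, 17), rep(1, 10))
  expect_equal(top_k_overlap(flags, 50), 0.66)
  expect_equal(top_k_overlap(rep(0, 60), 50), 0)
  expect_equal(top_k_overlap(rep(1, 50), 50), 1)
  # invariant to reordering below rank k
  expect_equal(top_k_overlap(c(flags[1:50], rev(flags[51:60])), 50), 0.66)
  expect_error(top_k_overlap(rep(1, 10), 50), "shorter")
})

test_that("roc_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(61, {
    s <- runif(200)
    l <- rbinom(200, 1, 0.3)
  })
  ref <- as.numeric(suppressMessages(pROC::auc(l, s, direction = "<")))
  expect_equal(roc_auc(s, l), ref, tolerance = 1e-12)
})
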