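test_that("cosine similarity matches hand values and conventions", {
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 1, 1)), 2 / sqrt(6))
  expect_equal(cosine_similarity(c(3, 1, 4), c(3, 1, 4)), 1)
  expect_equal(cosine_similarity(c(0, 0, 0), c(1, 2, 3)), 0)
  expect_equal(cosine_similarity(c(1, 2), c(0, 0)), 0)
  expect_error(cosine_similarity(1:3, 1:4), "length mismatch")
})

test_that("cosine similarity is scale-invariant and matches the loop oracle", {
  withr::with_seed(7, {
    for (i in 1:200) {
      n <- sample(1:20, 1)
      u <- round(runif(n) * 10, 3)
      v <- round(runif(n) * 10, 3)
      expect_equal(cosine_similarity(u, v), oracle_cosine(u, v),
                   tolerance = 1e-12)
      a <- runif(1, 0.1, 50)
      expect_equal(cosine_similarity(a * u, v), cosine_similarity(u, v),
                   tolerance = 1e-12)
      expect_gte(cosine_similarity(u, v), 0)
      expect_lte(cosine_similarity(u, v), 1 + 1e-12)
    }
  })
})

test_that("entity scores hit the identity and zero boundaries", {
  ev <- dplyr::bind_rows(
    person_all_four("T1"),
    coded_events("N1", ENTITIES, c("D9", "P9", "B9", "L9")))
  prof <- build_target_profile(ev, "T1", min_codes = 1)
  s <- entity_scores(ev, c("T1", "N1"), prof)
  # the training person matches its own single-person profile exactly
  expect_equal(unlist(s[s$person_id == "T1", c("s_diag", "s_proc",
                                               "s_presc", "s_lab")]),
               c(s_diag = 1, s_proc = 1, s_presc = 1, s_lab = 1))
  # a person with no featured codes scores zero everywhere
  expect_equal(unname(unlist(s[s$person_id == "N1", -1])), rep(0, 4))
})

test_that("vectorised entity scores equal per-person cosine of count vectors", {
  spec <- small_spec(seed = 17, n_participants = 10, n_registrants = 60)
  pop <- generate_population(spec)
  parts <- pop$labels$person_id[pop$labels$recruited == 1]
  prof <- build_target_profile(pop$events, parts)
  persons <- sample(pop$labels$person_id, 15)
  s <- entity_scores(pop$events, persons, prof)
  for (ent in ENTITIES) {
    col <- c(diagnosis = "s_diag", procedure = "s_proc",
             prescription = "s_presc", lab_test = "s_lab")[[ent]]
    for (p in persons[1:5]) {
      cv <- count_vector(pop$events, p, ent, prof[[ent]]$codes)
      expect_equal(s[[col]][s$person_id == p],
                   cosine_similarity(as.numeric(cv),
                                     as.numeric(prof[[ent]]$weights)),
                   tolerance = 1e-12)
    }
  }
})

test_that("participants score higher than background persons on average", {
  spec <- cohort_spec(n_registrants = 500, n_participants = 40,
                      vocab_size = 300, signature_codes = 10,
                      signature_penetrance = 0.9, background_carriage = 0.02,
                      seed = 23)
  pop <- generate_population(spec)
  parts <- pop$labels$person_id[pop$labels$recruited == 1]
  train <- parts[1:20]; held <- parts[21:40]
  prof <- build_target_profile(pop$events, train)
  bg <- setdiff(pop$labels$person_id, parts)[1:200]
  s <- entity_scores(pop$events, c(held, bg), prof)
  expect_gt(mean(s$s_diag[s$person_id %in% held]),
            mean(s$s_diag[s$person_id %in% bg]))
})

test_that("OLS weight fitting recovers constructed signals", {
  withr::with_seed(5, {
    n <- 60
    s <- tibble::tibble(s_diag = runif(n), s_proc = 0.5, s_presc = 0.5,
                        s_lab = 0.5)
    labels <- s$s_diag # perfectly predicted by the diagnosis score
    w <- fit_entity_weights(s, labels)
    expect_equal(unname(w$weights["diagnosis"]), 1, tolerance = 1e-8)
    # constant columns make the design rank-deficient; the minimum-norm
    # solution still reproduces the fitted values
    fitted <- final_score(s, w)
    expect_equal(fitted, labels, tolerance = 1e-8)

    # duplicating the whole design leaves the coefficients unchanged
    s2 <- tibble::tibble(s_diag = runif(n), s_proc = runif(n),
                         s_presc = runif(n), s_lab = runif(n))
    y2 <- rbinom(n, 1, 0.4)
    if (length(unique(y2)) > 1) {
      w1 <- fit_entity_weights(s2, y2)
      w2 <- fit_entity_weights(dplyr::bind_rows(s2, s2), c(y2, y2))
      expect_equal(w1$weights, w2$weights, tolerance = 1e-10)
      expect_equal(w1$intercept, w2$intercept, tolerance = 1e-10)
    }
  })
  expect_error(fit_entity_weights(tibble::tibble(s_diag = runif(6),
                                                 s_proc = 1, s_presc = 1,
                                                 s_lab = 1), rep(1, 6)),
               "identical")
})

test_that("the diagnosis weight dominates when only diagnosis carries signal", {
  hits <- 0L
  for (s in 1:10) {
    spec <- cohort_spec(n_registrants = 300, n_participants = 20,
                        vocab_size = 200, signature_codes = c(10, 0, 0, 0),
                        signature_penetrance = 0.9,
                        background_carriage = 0.02, seed = s)
    pop <- generate_population(spec)
    parts <- pop$labels$person_id[pop$labels$recruited == 1]
    prof <- build_target_profile(pop$events, parts[1:10])
    neg <- setdiff(pop$labels$person_id, parts)[1:100]
    ids <- c(parts[1:10], neg)
    sc <- entity_scores(pop$events, ids, prof)
    w <- fit_entity_weights(sc, as.integer(ids %in% parts))
    if (which.max(w$weights) == 1) hits <- hits + 1L
  }
  expect_gte(hits, 9)
})

test_that("final score and min-max scaling behave as specified", {
  s <- tibble::tibble(s_diag = c(1, 0.5), s_proc = c(1, 0.5),
                      s_presc = c(1, 0.5), s_lab = c(1, 0.5))
  w0 <- structure(list(intercept = 0.3,
                       weights = setNames(rep(0, 4), ENTITIES),
                       fit_meta = list(n_pos = 1, n_neg = 1)),
                  class = "entity_weights")
  expect_equal(final_score(s, w0), c(0.3, 0.3))
  w1 <- structure(list(intercept = 0,
                       weights = setNames(c(0.5, 0.2, 0.2, 0.1), ENTITIES),
                       fit_meta = list(n_pos = 1, n_neg = 1)),
                  class = "entity_weights")
  expect_equal(final_score(s, w1), c(1, 0.5))

  expect_equal(scale_scores(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(scale_scores(c(3, 3, 3)), c(0.5, 0.5, 0.5))
  withr::with_seed(9, {
    raw <- rnorm(50)
    expect_equal(rank(scale_scores(raw)), rank(raw)) # rank-preserving
  })
})
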