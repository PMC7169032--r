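# Deterministic sub-seed derivation: one master seed fans out to
# independent streams (folds, bootstrap, tie-breaks) while staying inside
# 32-bit integer range.
derive_seed <- function(master, stream) {
  as.integer((as.numeric(master) * 48271 + as.numeric(stream)) %% 2147483647)
}

#' Pipeline configuration
#'
#' Collects the tunable parameters of the cross-validated recruitment
#' pipeline in one object. Defaults follow the analysis design: support
#' threshold 0.8 with a minimum of 10 featured codes per entity, mean
#' occurrence counts as central tendency, the strict `all_four` inclusion
#' filter, 30,000 randomly drawn registrants per test set, 500 regression
#' negatives, 2000 bootstrap replicates, and a 0.01 cut-off grid.
#'
#' @param support_threshold Featured-code support fraction.
#' @param min_codes Minimum featured codes per entity.
#' @param top_up Top up to `min_codes` when fewer pass the threshold.
#' @param tendency Central tendency of occurrence counts, `"mean"` or
#'   `"median"`.
#' @param binary Use presence/absence instead of occurrence counts.
#' @param inclusion_mode `"all_four"` or `"any"`.
#' @param n_random Random registrants added to each test set.
#' @param n_negatives Registrant negatives for the weight regression,
#'   drawn outside the fold's test set.
#' @param n_replicates Bootstrap replicates for the AUC CI.
#' @param grid_step Cut-off sweep step.
#' @param n_random_refs Random realizations for the lower reference.
#' @param overlap_k Depth of the database-overlap metric.
#' @param seed Master seed; every random stage derives its stream from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(support_threshold = 0.8, min_codes = 10,
                            top_up = TRUE, tendency = "mean", binary = FALSE,
                            inclusion_mode = "all_four",
                            n_random = 30000, n_negatives = 500,
                            n_replicates = 2000, grid_step = 0.01,
                            n_random_refs = 1L, overlap_k = 50,
                            seed = 1L) {
  structure(list(support_threshold = support_threshold, min_codes = min_codes,
                 top_up = top_up, tendency = tendency, binary = binary,
                 inclusion_mode = inclusion_mode,
                 n_random = as.integer(n_random),
                 n_negatives = as.integer(n_negatives),
                 n_replicates = as.integer(n_replicates),
                 grid_step = grid_step,
                 n_random_refs = as.integer(n_random_refs),
                 overlap_k = as.integer(overlap_k),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Split participants into two folds
#'
#' Seeded random partition into halves differing in size by at most one;
#' each fold serves once as the training cases and once as part of the
#' test set.
#'
#' @param participants Character vector of participant ids (>= 2).
#' @param seed Integer seed.
#' @return List with `fold_A` and `fold_B`.
#' @export
split_two_fold <- function(participants, seed = 1L) {
  n <- length(participants)
  if (n < 2) stop("two-fold cross-validation needs at least 2 participants")
  shuffled <- withr::with_seed(seed, sample(participants))
  n_a <- ceiling(n / 2)
  list(fold_A = sort(shuffled[seq_len(n_a)]),
       fold_B = sort(shuffled[(n_a + 1):n]))
}

#' Assemble a fold's test set
#'
#' The test set is the union of (i) the held-out participants, (ii)
#' `n_random` registrants drawn at random from the pool, and (iii) every
#' database-identified person not recruited into the study. Duplicates
#' (a drawn registrant already in the database-identified set) appear once
#' and keep their database flag. Held-out participants are labelled
#' relevant; everyone else is not.
#'
#' @param test_participants Held-out participant ids.
#' @param registrant_pool Non-participant ids available for the random
#'   draw (disjoint from all participants).
#' @param db_identified Database-identified, non-recruited person ids.
#' @param n_random Number of registrants to draw (<= pool size).
#' @param seed Integer seed for the draw.
#' @return Tibble with `person_id`, `relevant` (0/1), `db_identified`
#'   (0/1).
#' @export
assemble_test_set <- function(test_participants, registrant_pool,
                              db_identified, n_random = 30000, seed = 1L) {
  if (length(intersect(test_participants, registrant_pool)) > 0) {
    stop("registrant pool must be disjoint from the participants")
  }
  if (n_random > length(registrant_pool)) {
    stop("n_random (", n_random, ") exceeds registrant pool size (",
         length(registrant_pool), ")")
  }
  drawn <- withr::with_seed(seed, sample(registrant_pool, n_random))
  ids <- unique(c(test_participants, drawn, db_identified))
  tibble(person_id = ids,
         relevant = as.integer(ids %in% test_participants),
         db_identified = as.integer(ids %in% db_identified))
}

# One fold end to end: profile from the training cases, test-set assembly,
# weight regression on training cases + sampled negatives, scoring,
# ranking, evaluation.
run_fold <- function(events, train_participants, test_participants,
                     registrant_pool, db_set, db_flagged, config,
                     fold_stream) {
  seed_assemble <- derive_seed(config$seed, fold_stream + 1L)
  seed_negs <- derive_seed(config$seed, fold_stream + 2L)
  seed_eval <- derive_seed(config$seed, fold_stream + 3L)
  seed_ties <- derive_seed(config$seed, fold_stream + 4L)

  profile <- build_target_profile(
    events, train_participants,
    support_threshold = config$support_threshold,
    min_codes = config$min_codes, top_up = config$top_up,
    tendency = config$tendency, binary = config$binary)

  test_set <- assemble_test_set(test_participants, registrant_pool,
                                db_set, n_random = config$n_random,
                                seed = seed_assemble)
  # db flag for held-out participants comes from the label table
  test_set$db_identified <- pmax(test_set$db_identified,
                                 as.integer(test_set$person_id %in% db_flagged))

  # regression negatives: registrants never entering this fold's test set
  reservoir <- setdiff(registrant_pool, test_set$person_id)
  n_neg <- min(config$n_negatives, length(reservoir))
  if (n_neg < 1) {
    stop("no registrants left outside the test set to serve as ",
         "regression negatives; lower n_random or n_negatives")
  }
  negatives <- withr::with_seed(seed_negs, sample(reservoir, n_neg))

  train_ids <- c(train_participants, negatives)
  stopifnot(length(intersect(train_ids, test_set$person_id)) == 0)
  train_scores <- entity_scores(events, train_ids, profile)
  train_labels <- as.integer(train_ids %in% train_participants)
  weights <- fit_entity_weights(train_scores, train_labels)

  scored <- score_persons(events, test_set$person_id, profile, weights)
  ranked <- rank_candidates(scored$person_id, scored$final_scaled,
                            relevant = test_set$relevant,
                            db_identified = test_set$db_identified,
                            tie_seed = seed_ties)
  evaluation <- evaluate_fold(ranked, n_replicates = config$n_replicates,
                              seed = seed_eval,
                              n_random_refs = config$n_random_refs,
                              overlap_k = config$overlap_k)
  scored$relevant <- test_set$relevant[match(scored$person_id,
                                             test_set$person_id)]
  scored$db_identified <- test_set$db_identified[match(scored$person_id,
                                                       test_set$person_id)]
  list(profile = profile, weights = weights, scores = scored,
       ranked = ranked, evaluation = evaluation)
}

#' Run the two-fold cross-validation for one project
#'
#' Splits the project's participants into two folds; for each fold the
#' other half's participants define the target profile and the weight
#' regression, and the held-out half is embedded in a large test set of
#' registrants plus the database-identified candidates. Every fold metric
#' is computed, then averaged across the two folds, and the fold
#' predictions are pooled for the project-level cut-off sweep. Fully
#' deterministic given the config seed.
#'
#' @param events Coded-event table for all persons.
#' @param labels Label tibble (`person_id`, `recruited`, `db_identified`;
#'   a `project_id` column is ignored here — see [run_suite()]).
#' @param config A [pipeline_config()].
#' @param project_id Identifier recorded in the result.
#' @param exclude_from_pool Extra person ids barred from the registrant
#'   pool (e.g. participants recruited into other projects of a suite).
#' @return List of class `project_result`: `folds` (two [run_fold] result
#'   lists), `evaluation` (two-row fold tibble), `averaged` (one-row mean
#'   of the folds), `pooled_cutoff` (sweep over both folds' predictions).
#' @export
run_project <- function(events, labels, config = pipeline_config(),
                        project_id = "project",
                        exclude_from_pool = character()) {
  included <- apply_inclusion_filter(events, mode = config$inclusion_mode)
  participants <- sort(intersect(labels$person_id[labels$recruited == 1],
                                 included))
  if (length(participants) < 2) {
    stop("project ", project_id, ": fewer than 2 included participants")
  }
  pool <- setdiff(included, c(labels$person_id[labels$recruited == 1],
                              exclude_from_pool))
  db_flagged <- labels$person_id[labels$db_identified == 1]
  db_set <- sort(intersect(setdiff(db_flagged,
                                   labels$person_id[labels$recruited == 1]),
                           included))

  folds <- split_two_fold(participants, seed = derive_seed(config$seed, 1L))
  fold_runs <- list(
    fold1 = run_fold(events, folds$fold_B, folds$fold_A, pool, db_set,
                     db_flagged, config, fold_stream = 100L),
    fold2 = run_fold(events, folds$fold_A, folds$fold_B, pool, db_set,
                     db_flagged, config, fold_stream = 200L)
  )
  ev <- dplyr::bind_rows(fold_runs$fold1$evaluation,
                         fold_runs$fold2$evaluation)
  ev <- dplyr::bind_cols(tibble(project_id = project_id, fold = 1:2), ev)
  num_cols <- names(ev)[vapply(ev, is.numeric, logical(1))]
  averaged <- dplyr::bind_cols(
    tibble(project_id = project_id),
    dplyr::summarise(ev, dplyr::across(dplyr::all_of(num_cols),
                                       ~ mean(.x, na.rm = FALSE))))
  averaged$fold <- NULL
  pooled <- optimal_cutoff(
    c(fold_runs$fold1$scores$final_scaled, fold_runs$fold2$scores$final_scaled),
    c(fold_runs$fold1$scores$relevant, fold_runs$fold2$scores$relevant),
    grid = seq(0, 1, by = config$grid_step))
  structure(list(project_id = project_id, folds = fold_runs,
                 evaluation = ev, averaged = averaged,
                 pooled_cutoff = pooled, config = config),
            class = "project_result")
}

#' @export
print.project_result <- function(x, ...) {
  cat("project_result '", x$project_id, "': fold AUCs ",
      sprintf("%.3f", x$evaluation$roc_auc[1]), " / ",
      sprintf("%.3f", x$evaluation$roc_auc[2]), ", average ",
      sprintf("%.3f", x$averaged$roc_auc), " (",
      auc_quality_label(x$averaged$roc_auc), ")\n", sep = "")
  invisible(x)
}

#' Run a suite of projects and aggregate their folds
#'
#' Analyses each project separately (see [run_project()]) and aggregates:
#' per-fold metrics for every project, per-project averages, grand means
#' over all ranking lists (2 folds x n projects) of ROC AUC, P5, P10, MAP,
#' MRR and top-50 overlap, and a cut-off sweep pooled over every fold's
#' predictions.
#'
#' @param events Coded-event table covering all projects' persons.
#' @param labels Label tibble with a `project_id` column.
#' @param config A [pipeline_config()]; each project derives its own seed
#'   stream from the master seed.
#' @return List of class `suite_result` with `projects`, `fold_table`,
#'   `project_table`, `grand` (one-row tibble of grand means) and
#'   `pooled_cutoff`.
#' @export
run_suite <- function(events, labels, config = pipeline_config()) {
  project_ids <- sort(unique(labels$project_id))
  if (length(project_ids) == 0) stop("labels carry no project_id")
  all_recruited <- unique(labels$person_id[labels$recruited == 1])
  results <- lapply(seq_along(project_ids), function(i) {
    pid <- project_ids[i]
    lab <- labels[labels$project_id == pid, , drop = FALSE]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 1000L + i)
    # participants of any project never enter another project's pool
    run_project(events, lab, cfg, project_id = pid,
                exclude_from_pool = all_recruited)
  })
  names(results) <- project_ids
  fold_table <- dplyr::bind_rows(lapply(results, `[[`, "evaluation"))
  project_table <- dplyr::bind_rows(lapply(results, `[[`, "averaged"))
  grand <- tibble(
    n_ranking_lists = nrow(fold_table),
    roc_auc = mean(fold_table$roc_auc),
    p5 = mean(fold_table$p5), p10 = mean(fold_table$p10),
    map = mean(fold_table$map), mrr = mean(fold_table$mrr),
    lower_p5 = mean(fold_table$lower_p5), lower_p10 = mean(fold_table$lower_p10),
    lower_map = mean(fold_table$lower_map), lower_mrr = mean(fold_table$lower_mrr),
    upper_p5 = mean(fold_table$upper_p5), upper_p10 = mean(fold_table$upper_p10),
    upper_map = mean(fold_table$upper_map), upper_mrr = mean(fold_table$upper_mrr),
    top50_overlap = mean(fold_table$top50_overlap)
  )
  all_scores <- unlist(lapply(results, function(r) {
    c(r$folds$fold1$scores$final_scaled, r$folds$fold2$scores$final_scaled)
  }), use.names = FALSE)
  all_labels <- unlist(lapply(results, function(r) {
    c(r$folds$fold1$scores$relevant, r$folds$fold2$scores$relevant)
  }), use.names = FALSE)
  pooled <- optimal_cutoff(all_scores, all_labels,
                           grid = seq(0, 1, by = config$grid_step))
  structure(list(projects = results, fold_table = fold_table,
                 project_table = project_table, grand = grand,
                 pooled_cutoff = pooled, config = config),
            class = "suite_result")
}

#' @export
print.suite_result <- function(x, ...) {
  cat("suite_result:", length(x$projects), "projects,",
      nrow(x$fold_table), "ranking lists\n")
  cat(sprintf("  grand mean ROC AUC %.3f (%s); P5 %.3f  P10 %.3f  MAP %.4f  MRR %.4f\n",
              x$grand$roc_auc, auc_quality_label(x$grand$roc_auc),
              x$grand$p5, x$grand$p10, x$grand$map, x$grand$mrr))
  cat(sprintf("  mean top-50 overlap with database set %.3f; pooled optimal cutoff %.2f (metric %.3f)\n",
              x$grand$top50_overlap, x$pooled_cutoff$cutoff,
              x$pooled_cutoff$max_metric))
  invisible(x)
}

#' Write a suite (or project) report to CSV files
#'
#' Emits `folds.csv` (one row per ranking list with every fold metric),
#' `projects.csv` (per-project fold averages), `grand.csv` (grand means)
#' and `cutoff_sweep.csv` (the pooled threshold sweep). Output is
#' byte-identical across reruns with the same config and seed.
#'
#' @param result A `suite_result` or `project_result`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(result, "project_result")) {
    fold_table <- result$evaluation
    project_table <- result$averaged
    grand <- result$averaged
    sweep <- result$pooled_cutoff$sweep
  } else {
    fold_table <- result$fold_table
    project_table <- result$project_table
    grand <- result$grand
    sweep <- result$pooled_cutoff$sweep
  }
  write.csv(fold_table, file.path(dir, "folds.csv"), row.names = FALSE)
  write.csv(project_table, file.path(dir, "projects.csv"), row.names = FALSE)
  write.csv(grand, file.path(dir, "grand.csv"), row.names = FALSE)
  write.csv(sweep, file.path(dir, "cutoff_sweep.csv"), row.names = FALSE)
  invisible(dir)
}
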