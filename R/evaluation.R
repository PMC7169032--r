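#' ROC AUC by the Mann-Whitney formulation
#'
#' The probability that a randomly chosen positive (recruited participant)
#' scores higher than a randomly chosen negative, ties counting 1/2 — equal
#' to the trapezoidal area under the ROC curve. Computed from midranks, so
#' it is exact under ties and O(n log n).
#'
#' @param scores Numeric vector.
#' @param labels 0/1 vector, same length; both classes must be present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_auc needs both classes present")
  }
  r <- rank(scores) # midranks on ties
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Qualitative band for a ROC AUC value
#'
#' Standard interpretation scheme: 0.9-1 excellent, 0.8-0.9 good, 0.7-0.8
#' fair, 0.6-0.7 poor, 0.5-0.6 fail; below 0.5 the classifier is worse
#' than a random guess.
#'
#' @param auc AUC value in [0, 1].
#' @return One of `"excellent"`, `"good"`, `"fair"`, `"poor"`, `"fail"`,
#'   `"worse_than_random"`.
#' @export
auc_quality_label <- function(auc) {
  if (is.na(auc) || auc < 0 || auc > 1) stop("auc must lie in [0, 1]")
  if (auc >= 0.9) "excellent"
  else if (auc >= 0.8) "good"
  else if (auc >= 0.7) "fair"
  else if (auc >= 0.6) "poor"
  else if (auc >= 0.5) "fail"
  else "worse_than_random"
}

#' Bootstrap confidence interval for the ROC AUC
#'
#' Percentile interval from bootstrap replicates of the AUC. By default the
#' resampling is stratified: positives and negatives are resampled
#' separately with replacement, so every replicate retains both classes.
#' When either stratum has fewer than 2 members no stable interval exists
#' and `c(NA, NA)` is returned (the NA marker degenerate cohorts produce).
#'
#' @param scores,labels As in [roc_auc()].
#' @param n_replicates Bootstrap replicates (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; the interval is deterministic given it.
#' @param stratified Resample within classes (default) or over all rows.
#' @return Named numeric `c(ci_low, ci_high)`, possibly `NA`.
#' @export
bootstrap_ci <- function(scores, labels, n_replicates = 2000, level = 0.95,
                         seed = 1L, stratified = TRUE) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) < 2 || length(neg) < 2) {
    return(c(ci_low = NA_real_, ci_high = NA_real_))
  }
  aucs <- withr::with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      if (stratified) {
        p <- pos[sample.int(length(pos), replace = TRUE)]
        n <- neg[sample.int(length(neg), replace = TRUE)]
      } else {
        idx <- sample.int(length(scores), replace = TRUE)
        p <- scores[idx][labels[idx] == 1]
        n <- scores[idx][labels[idx] == 0]
        if (length(p) == 0 || length(n) == 0) return(NA_real_)
      }
      roc_auc(c(p, n), rep(1:0, c(length(p), length(n))))
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- quantile(aucs, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  c(ci_low = ci[1], ci_high = ci[2])
}

#' Cut-off maximizing sensitivity plus specificity
#'
#' Sweeps thresholds over a grid (0 to 1 in steps of 0.01 by default,
#' matching a percent axis); at each threshold persons scoring at or above
#' it are called positive, and the performance metric is the scaled sum of
#' sensitivity and specificity — implemented as their arithmetic mean so
#' the metric lies in [0, 1]; the argmax is unaffected by the positive
#' affine scaling. The smallest maximizing threshold is returned.
#'
#' @param scores Scaled scores in [0, 1].
#' @param labels 0/1 vector; both classes present.
#' @param grid Threshold grid.
#' @return List with `cutoff`, `max_metric`, and the full `sweep` tibble
#'   (threshold, sensitivity, specificity, metric).
#' @export
optimal_cutoff <- function(scores, labels, grid = seq(0, 1, by = 0.01)) {
  labels <- as.integer(labels)
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("optimal_cutoff needs both classes present")
  }
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  sens <- vapply(grid, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(grid, function(t) mean(neg < t), numeric(1))
  metric <- (sens + spec) / 2
  best <- which.max(metric) # which.max returns the first (smallest t)
  list(cutoff = grid[best], max_metric = metric[best],
       sweep = tibble(threshold = grid, sensitivity = sens,
                      specificity = spec, metric = metric))
}

#' Build a ranking list from scaled scores
#'
#' Orders persons by decreasing score. Tied scores are broken by a seeded
#' random shuffle applied before the stable sort — deterministic given
#' `tie_seed` yet unbiased with respect to identity.
#'
#' @param person_id Character vector.
#' @param final_scaled Scaled scores.
#' @param relevant 0/1 recruitment flags.
#' @param db_identified 0/1 database-query flags.
#' @param tie_seed Integer seed for tie breaking.
#' @return Tibble of class `ranked_list` with columns `rank`, `person_id`,
#'   `final_scaled`, `relevant`, `db_identified`, scores non-increasing.
#' @export
rank_candidates <- function(person_id, final_scaled, relevant,
                            db_identified = NULL, tie_seed = 1L) {
  n <- length(person_id)
  stopifnot(length(final_scaled) == n, length(relevant) == n)
  if (is.null(db_identified)) db_identified <- rep(0L, n)
  shuffle <- withr::with_seed(tie_seed, sample.int(n))
  ord <- shuffle[order(-final_scaled[shuffle])] # stable sort after shuffle
  out <- tibble(rank = seq_len(n),
                person_id = person_id[ord],
                final_scaled = final_scaled[ord],
                relevant = as.integer(relevant[ord]),
                db_identified = as.integer(db_identified[ord]))
  class(out) <- c("ranked_list", class(out))
  out
}

#' Precision at rank k
#'
#' Fraction of the first `k` ranked persons that are relevant (recruited).
#'
#' @param ranked A [rank_candidates()] tibble, or a 0/1 relevance vector in
#'   rank order.
#' @param k Depth (the study reports k = 5 and k = 10).
#' @return Precision in [0, 1].
#' @export
precision_at_k <- function(ranked, k) {
  rel <- relevance_of(ranked)
  if (length(rel) < k) {
    stop("ranking list shorter than k = ", k)
  }
  mean(rel[seq_len(k)])
}

#' Average precision of a ranking list
#'
#' Mean, over the relevant items, of the precision at each relevant item's
#' rank — a whole-list quality measure that is 1 exactly when all relevant
#' items occupy the top ranks.
#'
#' @inheritParams precision_at_k
#' @return Average precision in (0, 1].
#' @export
average_precision <- function(ranked) {
  rel <- relevance_of(ranked)
  hits <- which(rel == 1)
  if (length(hits) == 0) stop("no relevant item in the list")
  mean(seq_along(hits) / hits)
}

#' Reciprocal rank of the first relevant item
#'
#' 1 / rank of the first recruited person retrieved — the utility of the
#' list for finding a single suitable participant.
#'
#' @inheritParams precision_at_k
#' @return Reciprocal rank in (0, 1].
#' @export
reciprocal_rank <- function(ranked) {
  rel <- relevance_of(ranked)
  hits <- which(rel == 1)
  if (length(hits) == 0) stop("no relevant item in the list")
  1 / hits[1]
}

relevance_of <- function(ranked) {
  if (is.data.frame(ranked)) as.integer(ranked$relevant) else as.integer(ranked)
}

#' Best-possible and random-list reference values
#'
#' Upper references are the metrics of the ideal list with all relevant
#' items at ranks 1..n_relevant (closed forms: P@k = min(n, k)/k, MAP = MRR
#' = 1). Lower references are the metrics of seeded uniformly random
#' permutations — one by default, or the mean over `n_random_refs`
#' realizations.
#'
#' @param n_relevant Number of relevant items (>= 1).
#' @param list_length Total list length (>= n_relevant).
#' @param seed Seed for the random list.
#' @param n_random_refs Random realizations to average for the lower
#'   reference (default 1).
#' @return List with `upper` and `lower`, each holding `p5`, `p10`, `map`,
#'   `mrr`.
#' @export
reference_bounds <- function(n_relevant, list_length, seed = 1L,
                             n_random_refs = 1L) {
  stopifnot(n_relevant >= 1, n_relevant <= list_length)
  upper <- list(p5 = min(n_relevant, 5) / 5,
                p10 = min(n_relevant, 10) / 10,
                map = 1, mrr = 1)
  lowers <- withr::with_seed(seed, {
    lapply(seq_len(n_random_refs), function(i) {
      rel <- integer(list_length)
      rel[sample.int(list_length, n_relevant)] <- 1L
      list(p5 = precision_at_k(rel, min(5, list_length)),
           p10 = precision_at_k(rel, min(10, list_length)),
           map = average_precision(rel),
           mrr = reciprocal_rank(rel))
    })
  })
  lower <- lapply(c(p5 = "p5", p10 = "p10", map = "map", mrr = "mrr"),
                  function(f) mean(vapply(lowers, `[[`, numeric(1), f)))
  list(upper = upper, lower = lower)
}

#' Overlap of the top of the ranking with the database-identified set
#'
#' Proportion of the top `k` ranked persons that were also identified by
#' the database-query search strategy — the consistency measure between
#' case-based reasoning and database search.
#'
#' @param ranked A [rank_candidates()] tibble, or a 0/1 db-flag vector in
#'   rank order.
#' @param k Depth (default 50).
#' @return Proportion in [0, 1].
#' @export
top_k_overlap <- function(ranked, k = 50) {
  flags <- if (is.data.frame(ranked)) as.integer(ranked$db_identified)
           else as.integer(ranked)
  if (length(flags) < k) stop("ranking list shorter than k = ", k)
  mean(flags[seq_len(k)])
}

#' Evaluate one cross-validation fold's ranking list
#'
#' Computes every fold-level metric: ROC AUC with stratified bootstrap CI
#' and quality band, the optimal cut-off sweep, P5/P10/MAP/MRR with their
#' Upper and Lower references, and the top-50 overlap with the
#' database-identified set.
#'
#' @param ranked A [rank_candidates()] tibble.
#' @param n_replicates Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap and the random lower reference.
#' @param n_random_refs Random realizations for the lower reference.
#' @param overlap_k Depth of the database-overlap metric (default 50).
#' @return One-row tibble of class `fold_evaluation`.
#' @export
evaluate_fold <- function(ranked, n_replicates = 2000, seed = 1L,
                          n_random_refs = 1L, overlap_k = 50) {
  scores <- ranked$final_scaled
  labels <- ranked$relevant
  auc <- roc_auc(scores, labels)
  ci <- bootstrap_ci(scores, labels, n_replicates = n_replicates, seed = seed)
  cut <- optimal_cutoff(scores, labels)
  n_rel <- sum(labels == 1)
  refs <- reference_bounds(n_rel, length(labels), seed = seed,
                           n_random_refs = n_random_refs)
  out <- tibble(
    n_test = length(labels), n_relevant = n_rel,
    roc_auc = auc, ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
    quality = auc_quality_label(auc),
    optimal_cutoff = cut$cutoff, cutoff_metric = cut$max_metric,
    p5 = precision_at_k(ranked, 5), p10 = precision_at_k(ranked, 10),
    map = average_precision(ranked), mrr = reciprocal_rank(ranked),
    upper_p5 = refs$upper$p5, upper_p10 = refs$upper$p10,
    upper_map = refs$upper$map, upper_mrr = refs$upper$mrr,
    lower_p5 = refs$lower$p5, lower_p10 = refs$lower$p10,
    lower_map = refs$lower$map, lower_mrr = refs$lower$mrr,
    top50_overlap = top_k_overlap(ranked, k = overlap_k)
  )
  class(out) <- c("fold_evaluation", class(out))
  out
}
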