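#' Cosine similarity between two nonnegative vectors
#'
#' Orientation-based similarity, `u.v / (|u||v|)`; with nonnegative entries
#' the result lies in [0, 1]. If either vector is all-zero the similarity
#' is defined as 0 (maximally dissimilar), so persons carrying none of the
#' featured codes sink in the ranking.
#'
#' @param u,v Numeric vectors of equal length with nonnegative entries.
#' @return Similarity in [0, 1].
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 1, 1)) # 2 / sqrt(6)
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    stop("length mismatch: ", length(u), " vs ", length(v))
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

score_cols <- c(diagnosis = "s_diag", procedure = "s_proc",
                prescription = "s_presc", lab_test = "s_lab")

#' Per-entity similarity scores against a target profile
#'
#' For each person and each of the four entities, the cosine similarity
#' between the person's occurrence-count vector over the entity's featured
#' codes and the profile's weight vector. Each person is thus represented
#' by four similarity scores in [0, 1]. Entities with an empty featured
#' list, or persons with no featured-code events, score 0.
#'
#' @param events Coded-event table.
#' @param persons Character vector of person ids to score.
#' @param profile A [build_target_profile()] result.
#' @return Tibble with columns `person_id`, `s_diag`, `s_proc`, `s_presc`,
#'   `s_lab`.
#' @export
entity_scores <- function(events, persons, profile) {
  stopifnot(inherits(profile, "target_profile"))
  binary <- isTRUE(attr(profile, "binary"))
  out <- tibble(person_id = persons)
  for (ent in ENTITIES) {
    p <- profile[[ent]]
    col <- score_cols[[ent]]
    if (length(p$codes) == 0 || sum(p$weights^2) == 0) {
      out[[col]] <- rep(0, length(persons))
      next
    }
    m <- count_matrix(events, persons, ent, p$codes, binary = binary)
    w <- as.numeric(p$weights)
    num <- as.numeric(m %*% w)
    row_norm <- sqrt(Matrix::rowSums(m^2))
    s <- ifelse(row_norm > 0, num / (row_norm * sqrt(sum(w^2))), 0)
    out[[col]] <- as.numeric(s)
  }
  out
}

#' Fit the four entity weights by linear regression
#'
#' Ordinary least squares of the 0/1 recruitment label on the four entity
#' similarity scores, with intercept. The training design needs both
#' classes: the training-fold participants supply the positives and a
#' seeded sample of registrants outside the fold's test set supplies the
#' negatives. Rank-deficient designs (e.g. a constant score column) are
#' solved by the minimum-norm least-squares solution.
#'
#' @param scores Tibble from [entity_scores()] (columns `s_diag`, `s_proc`,
#'   `s_presc`, `s_lab`).
#' @param labels Numeric 0/1 vector, one per row of `scores`.
#' @return Object of class `entity_weights`: `intercept`, `weights` (named
#'   by entity), `fit_meta` (n_pos, n_neg).
#' @export
fit_entity_weights <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (nrow(scores) != length(labels)) stop("scores/labels length mismatch")
  if (nrow(scores) < 5) stop("need at least 5 training rows")
  if (length(unique(labels)) < 2) {
    stop("all training labels identical; add negative examples ",
         "(registrants outside the test set) to identify the weights")
  }
  x <- cbind(1, as.matrix(scores[, unname(score_cols)]))
  qx <- qr(x)
  beta <- if (qx$rank < ncol(x)) {
    as.numeric(MASS::ginv(x) %*% labels)
  } else {
    as.numeric(qr.coef(qx, labels))
  }
  structure(list(intercept = beta[1],
                 weights = setNames(beta[-1], ENTITIES),
                 fit_meta = list(n_pos = sum(labels == 1),
                                 n_neg = sum(labels == 0))),
            class = "entity_weights")
}

#' @export
print.entity_weights <- function(x, ...) {
  cat("entity_weights (OLS,", x$fit_meta$n_pos, "pos /",
      x$fit_meta$n_neg, "neg)\n")
  print(round(c(intercept = x$intercept, x$weights), 4))
  invisible(x)
}

#' Combine entity similarities into the raw prediction score
#'
#' `intercept + sum_e w_e * s_e` for each person.
#'
#' @param scores Tibble from [entity_scores()].
#' @param weights An [fit_entity_weights()] result.
#' @return Numeric vector of raw final scores, one per row.
#' @export
final_score <- function(scores, weights) {
  stopifnot(inherits(weights, "entity_weights"))
  s <- as.matrix(scores[, unname(score_cols)])
  as.numeric(weights$intercept + s %*% weights$weights)
}

#' Min-max scale raw scores to [0, 1] within a test set
#'
#' `(x - min) / (max - min)` over the test set; the map is strictly
#' monotone, so rankings and ROC AUC are unchanged. When all raw scores are
#' equal every scaled score is 0.5.
#'
#' @param raw Numeric vector (length >= 1).
#' @return Scaled scores in [0, 1].
#' @export
scale_scores <- function(raw) {
  if (length(raw) == 0) stop("need at least one score")
  rng <- range(raw)
  if (rng[1] == rng[2]) return(rep(0.5, length(raw)))
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Score a test set end to end
#'
#' Convenience wrapper: entity similarities, weighted combination and
#' min-max scaling for a set of persons.
#'
#' @param events Coded-event table.
#' @param persons Person ids to score.
#' @param profile Target profile.
#' @param weights Fitted entity weights.
#' @return Tibble with `person_id`, the four `s_*` columns, `final_raw`,
#'   `final_scaled`.
#' @export
score_persons <- function(events, persons, profile, weights) {
  sc <- entity_scores(events, persons, profile)
  sc$final_raw <- final_score(sc, weights)
  sc$final_scaled <- scale_scores(sc$final_raw)
  sc
}
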