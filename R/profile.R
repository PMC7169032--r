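#' Select featured codes for one entity
#'
#' Featured codes are chosen by their support among the training
#' participants: a code's support is the fraction of training persons
#' carrying it at least once (repeat occurrences count once here). The
#' selection rule requires a minimum of `min_codes` codes shared by at
#' least `support_threshold` of the participants:
#'
#' * if at least `min_codes` codes reach the threshold, all of them are
#'   returned (`threshold_met`);
#' * if some but fewer than `min_codes` do, the list is topped up to
#'   `min_codes` with the highest-support codes overall, which necessarily
#'   include the threshold-passers (`topped_up`); `top_up = FALSE` instead
#'   returns only the threshold-passers;
#' * if no code reaches the threshold (sparse data), every observed code is
#'   retained (`all_retained`).
#'
#' Codes are ordered by decreasing support, ties broken lexicographically,
#' so selection is deterministic.
#'
#' @param events Coded-event table.
#' @param training_persons Non-empty character vector of person ids.
#' @param entity One of [ENTITIES].
#' @param support_threshold Support fraction required (default 0.8).
#' @param min_codes Minimum featured-code count before topping up (10).
#' @param top_up Top up to `min_codes` when fewer pass the threshold.
#' @return List with `codes` (ordered character), `support` (named numeric,
#'   same order) and `meta` (one of `"threshold_met"`, `"topped_up"`,
#'   `"all_retained"`).
#' @export
select_feature_codes <- function(events, training_persons, entity,
                                 support_threshold = 0.8, min_codes = 10,
                                 top_up = TRUE) {
  if (length(training_persons) == 0) stop("empty training set")
  sub <- events[events$entity == entity &
                  events$person_id %in% training_persons, , drop = FALSE]
  carriers <- dplyr::distinct(as_tibble(sub), .data$person_id, .data$code)
  support <- table(carriers$code) / length(training_persons)
  support <- setNames(as.numeric(support), names(support))
  if (length(support) == 0) {
    # training persons carry no events of this entity: nothing to feature
    return(list(codes = character(), support = numeric(),
                meta = "all_retained"))
  }
  # decreasing support, lexicographic within ties
  ord <- order(-support, names(support))
  support <- support[ord]
  passing <- names(support)[support >= support_threshold]
  if (length(passing) >= min_codes) {
    codes <- passing
    meta <- "threshold_met"
  } else if (length(passing) > 0) {
    if (top_up) {
      codes <- names(support)[seq_len(min(min_codes, length(support)))]
      meta <- "topped_up"
    } else {
      codes <- passing
      meta <- "threshold_met"
    }
  } else {
    codes <- names(support)
    meta <- "all_retained"
  }
  list(codes = codes, support = support[codes], meta = meta)
}

#' Build the target profile of an idealised participant
#'
#' The target profile holds, per entity, the featured codes and a weight
#' per code: the central tendency (mean by default, optionally median) of
#' the code's occurrence count across the training participants,
#' non-carriers contributing zeros. With a single training person the
#' profile equals that person's count vector.
#'
#' @param events Coded-event table.
#' @param training_persons Character vector of person ids (>= 1).
#' @param support_threshold,min_codes,top_up Passed to
#'   [select_feature_codes()].
#' @param tendency `"mean"` (default) or `"median"`.
#' @param binary Count presence instead of occurrence multiplicity.
#' @return Object of class `target_profile`: per entity a list with
#'   `codes`, `weights`, `support`, `meta`; plus attributes recording the
#'   selection parameters.
#' @export
build_target_profile <- function(events, training_persons,
                                 support_threshold = 0.8, min_codes = 10,
                                 top_up = TRUE, tendency = c("mean", "median"),
                                 binary = FALSE) {
  tendency <- match.arg(tendency)
  if (length(training_persons) == 0) stop("empty training set")
  center <- if (tendency == "mean") Matrix::colMeans else matrix_col_medians
  prof <- lapply(ENTITIES, function(ent) {
    sel <- select_feature_codes(events, training_persons, ent,
                                support_threshold, min_codes, top_up)
    if (length(sel$codes) == 0) {
      return(list(codes = character(), weights = numeric(),
                  support = numeric(), meta = sel$meta))
    }
    m <- count_matrix(events, training_persons, ent, sel$codes, binary = binary)
    w <- as.numeric(center(m))
    list(codes = sel$codes, weights = setNames(w, sel$codes),
         support = sel$support, meta = sel$meta)
  })
  names(prof) <- ENTITIES
  structure(prof, class = "target_profile",
            tendency = tendency, binary = binary,
            support_threshold = support_threshold, min_codes = min_codes,
            n_training = length(training_persons))
}

matrix_col_medians <- function(m) {
  apply(as.matrix(m), 2, median)
}

#' @export
print.target_profile <- function(x, ...) {
  cat("target_profile (", attr(x, "tendency"), "of occurrence counts,",
      attr(x, "n_training"), "training persons )\n")
  for (ent in ENTITIES) {
    cat(sprintf("  %-12s %3d featured codes [%s]\n", ent,
                length(x[[ent]]$codes), x[[ent]]$meta))
  }
  invisible(x)
}

#' Serialize a target profile to CSV and back
#'
#' Long CSV with columns `entity, code, weight, support, selection_meta`,
#' for inspection and reuse of a fitted profile.
#'
#' @param profile A `target_profile`.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  rows <- dplyr::bind_rows(lapply(ENTITIES, function(ent) {
    p <- profile[[ent]]
    if (length(p$codes) == 0) return(NULL)
    tibble(entity = ent, code = p$codes,
           weight = as.numeric(p$weights),
           support = as.numeric(p$support),
           selection_meta = p$meta)
  }))
  write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- read.csv(path, colClasses = c(entity = "character", code = "character",
                                      weight = "numeric", support = "numeric",
                                      selection_meta = "character"),
                 fileEncoding = "UTF-8")
  prof <- lapply(ENTITIES, function(ent) {
    p <- df[df$entity == ent, , drop = FALSE]
    list(codes = p$code, weights = setNames(p$weight, p$code),
         support = setNames(p$support, p$code),
         meta = if (nrow(p) > 0) p$selection_meta[1] else "all_retained")
  })
  names(prof) <- ENTITIES
  structure(prof, class = "target_profile",
            tendency = NA_character_, binary = NA,
            support_threshold = NA_real_, min_codes = NA_integer_,
            n_training = NA_integer_)
}
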