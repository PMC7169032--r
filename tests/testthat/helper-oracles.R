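# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the vectorised/rank-based code paths.

# cosine by explicit summation loops
oracle_cosine <- function(u, v) {
  dot <- 0; nu <- 0; nv <- 0
  for (i in seq_along(u)) {
    dot <- dot + u[i] * v[i]
    nu <- nu + u[i]^2
    nv <- nv + v[i]^2
  }
  if (nu == 0 || nv == 0) return(0)
  dot / (sqrt(nu) * sqrt(nv))
}

# AUC by enumerating every (positive, negative) pair, ties credited 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# featured-code selection by exhaustive support enumeration
oracle_select <- function(person_codes, support_threshold, min_codes) {
  all_codes <- sort(unique(unlist(person_codes)))
  support <- vapply(all_codes, function(cd) {
    mean(vapply(person_codes, function(p) cd %in% p, logical(1)))
  }, numeric(1))
  ord <- order(-support, all_codes)
  all_codes <- all_codes[ord]; support <- support[ord]
  passing <- all_codes[support >= support_threshold]
  if (length(passing) >= min_codes) {
    list(codes = passing, meta = "threshold_met")
  } else if (length(passing) > 0) {
    list(codes = all_codes[seq_len(min(min_codes, length(all_codes)))],
         meta = "topped_up")
  } else {
    list(codes = all_codes, meta = "all_retained")
  }
}

# events table from a named list of per-person code vectors, one entity
events_from_codes <- function(person_codes, entity = "diagnosis") {
  coded_events(rep(names(person_codes), lengths(person_codes)),
               entity, unlist(person_codes, use.names = FALSE))
}

# minimal person passing the all_four filter, with given extra codes
person_all_four <- function(id, extra = NULL) {
  base <- coded_events(id, ENTITIES, c("D1", "P1", "B1", "L1"))
  if (is.null(extra)) base else dplyr::bind_rows(base, extra)
}

# small synthetic study conditions used across pipeline tests
small_spec <- function(seed, n_participants = 20, n_registrants = 600) {
  cohort_spec(n_registrants = n_registrants, n_participants = n_participants,
              vocab_size = 200, events_per_person = 10, signature_codes = 12,
              seed = seed)
}

small_config <- function(seed, n_random = 400, n_negatives = 150,
                         n_replicates = 100) {
  pipeline_config(n_random = n_random, n_negatives = n_negatives,
                  n_replicates = n_replicates, seed = seed)
}
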