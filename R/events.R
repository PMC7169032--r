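#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median quantile rbinom rnorm rpois runif sd setNames
#' @importFrom utils read.csv write.csv count.fields
NULL

#' The four coded clinical entities
#'
#' Coded EHR events belong to exactly one of four entities: diagnoses
#' (ICD-10), surgical procedures (OPCS-4), drug prescriptions (BNF codes)
#' and laboratory tests (read codes). Codes are treated as opaque strings;
#' no dictionary validation or hierarchy rollup is performed.
#'
#' @format Character vector of length 4.
#' @export
ENTITIES <- c("diagnosis", "procedure", "prescription", "lab_test")

#' Construct a table of coded clinical events
#'
#' A coded event is one clinical fact in long entity-attribute-value (EAV)
#' form: a person, an entity, a code, and optionally a calendar date, a
#' numeric laboratory result (`value`, lab tests only) and a dispensed
#' amount (`quantity`, prescriptions only).
#'
#' @param person_id Character vector of person identifiers.
#' @param entity Character vector; each element one of [ENTITIES].
#' @param code Character vector of codes in the entity's code system.
#' @param event_date Optional `Date` vector (`NA` allowed).
#' @param value Optional numeric lab results; only lab-test events may carry
#'   a non-missing value.
#' @param quantity Optional numeric dispensed amounts; only prescription
#'   events may carry a non-missing quantity.
#' @param allow_incomplete Keep rows with an empty code (e.g. lab results
#'   with an incomplete test description) instead of erroring. Such rows are
#'   dropped by [apply_inclusion_filter()].
#' @return A tibble with columns `person_id`, `entity`, `code`,
#'   `event_date`, `value`, `quantity`.
#' @examples
#' coded_events(c("A", "A"), "diagnosis", c("J18", "E11"))
#' @export
coded_events <- function(person_id, entity, code,
                         event_date = NULL, value = NULL, quantity = NULL,
                         allow_incomplete = FALSE) {
  n <- max(length(person_id), length(entity), length(code))
  ev <- tibble(
    person_id = as.character(rep_len(person_id, n)),
    entity = as.character(rep_len(entity, n)),
    code = as.character(rep_len(code, n)),
    event_date = if (is.null(event_date)) as.Date(rep(NA, n)) else
      as.Date(rep_len(event_date, n)),
    value = if (is.null(value)) rep(NA_real_, n) else
      as.numeric(rep_len(value, n)),
    quantity = if (is.null(quantity)) rep(NA_real_, n) else
      as.numeric(rep_len(quantity, n))
  )
  validate_events(ev, allow_incomplete = allow_incomplete)
}

#' Validate a coded-event table
#'
#' Checks the invariants of the event model: known entities, non-empty
#' codes (unless `allow_incomplete`), `value` only on lab tests and
#' `quantity` only on prescriptions.
#'
#' @param events A data frame of events (see [coded_events()]).
#' @inheritParams coded_events
#' @return The events as a tibble, invisibly checked.
#' @export
validate_events <- function(events, allow_incomplete = FALSE) {
  events <- as_tibble(events)
  required <- c("person_id", "entity", "code")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    stop("event table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(events$entity), ENTITIES)
  if (length(bad) > 0) {
    stop("unknown entity value(s): ", paste(bad, collapse = ", "),
         "; must be one of: ", paste(ENTITIES, collapse = ", "))
  }
  empty_code <- is.na(events$code) | events$code == ""
  if (any(empty_code) && !allow_incomplete) {
    stop(sum(empty_code), " event(s) have an empty code; ",
         "use allow_incomplete = TRUE to keep them for filtering")
  }
  if (!"event_date" %in% names(events)) events$event_date <- as.Date(NA)
  if (!"value" %in% names(events)) events$value <- NA_real_
  if (!"quantity" %in% names(events)) events$quantity <- NA_real_
  if (any(!is.na(events$value) & events$entity != "lab_test")) {
    stop("'value' is permitted only on lab_test events")
  }
  if (any(!is.na(events$quantity) & events$entity != "prescription")) {
    stop("'quantity' is permitted only on prescription events")
  }
  events[, c("person_id", "entity", "code", "event_date", "value", "quantity")]
}

#' Reshape wide per-person code rows into long EAV events
#'
#' Source extracts often arrive in wide form, one row per person per record
#' with a variable number of code cells (e.g. a hospital episode listing
#' pneumonia, diabetes and hypertension as three diagnosis columns). This
#' turns each non-empty code cell into one coded event, preserving the
#' within-row order of codes.
#'
#' @param wide_rows Data frame with columns `person_id`, `entity`, and any
#'   number of further columns holding code strings; empty strings and `NA`
#'   cells are dropped.
#' @return A tibble of coded events, one per non-empty code cell.
#' @examples
#' w <- data.frame(person_id = "A", entity = "diagnosis",
#'                 c1 = "J18", c2 = "E11", c3 = "I10")
#' widen_to_long(w)
#' @export
widen_to_long <- function(wide_rows) {
  wide_rows <- as.data.frame(wide_rows)
  if (!all(c("person_id", "entity") %in% names(wide_rows))) {
    stop("wide table needs 'person_id' and 'entity' columns")
  }
  bad <- setdiff(unique(as.character(wide_rows$entity)), ENTITIES)
  if (length(bad) > 0) {
    stop("unknown entity value(s): ", paste(bad, collapse = ", "),
         "; must be one of: ", paste(ENTITIES, collapse = ", "))
  }
  code_cols <- setdiff(names(wide_rows), c("person_id", "entity"))
  if (length(code_cols) == 0 || nrow(wide_rows) == 0) {
    return(coded_events(character(), character(), character()))
  }
  # row-major traversal keeps within-row code order
  per_row <- lapply(seq_len(nrow(wide_rows)), function(i) {
    codes <- as.character(unlist(wide_rows[i, code_cols], use.names = FALSE))
    codes <- codes[!is.na(codes) & codes != ""]
    if (length(codes) == 0) return(NULL)
    tibble(person_id = as.character(wide_rows$person_id[i]),
           entity = as.character(wide_rows$entity[i]),
           code = codes)
  })
  long <- dplyr::bind_rows(per_row)
  if (nrow(long) == 0) return(coded_events(character(), character(), character()))
  coded_events(long$person_id, long$entity, long$code)
}

#' Apply the cohort inclusion filter
#'
#' Persons with no meaningful clinical data are excluded before analysis.
#' Under the default `all_four` mode a person is retained only with at
#' least one event in each of the four entities (the criterion applied to
#' both participants and the registrant pool); under `any`, at least one
#' event in any entity suffices. Lab events with an incomplete test
#' description (empty code) are ignored when counting coverage.
#'
#' @param events Coded-event table (empty codes tolerated).
#' @param mode `"all_four"` (default) or `"any"`.
#' @return Character vector of retained person ids (sorted).
#' @export
apply_inclusion_filter <- function(events, mode = c("all_four", "any")) {
  mode <- match.arg(mode)
  events <- validate_events(events, allow_incomplete = TRUE)
  events <- events[!is.na(events$code) & events$code != "", , drop = FALSE]
  if (nrow(events) == 0) return(character())
  cover <- dplyr::distinct(events, .data$person_id, .data$entity) |>
    dplyr::count(.data$person_id, name = "n_entities")
  keep <- if (mode == "all_four") {
    cover$person_id[cover$n_entities == length(ENTITIES)]
  } else {
    cover$person_id
  }
  sort(keep)
}

#' Occurrence counts of a code list for one person
#'
#' Tallies how often each code in `codes` occurs among one person's events
#' of one entity. Codes the person never carries count 0. With
#' `binary = TRUE` counts are collapsed to presence/absence.
#'
#' @param events Coded-event table.
#' @param person A single person id.
#' @param entity One of [ENTITIES].
#' @param codes Ordered, non-empty character vector of codes.
#' @param binary Collapse counts to 0/1 presence.
#' @return Named integer vector of length `length(codes)`.
#' @examples
#' ev <- coded_events("A", "diagnosis", c("X1", "X1", "X2"))
#' count_vector(ev, "A", "diagnosis", c("X1", "X2", "X3"))
#' @export
count_vector <- function(events, person, entity, codes, binary = FALSE) {
  stopifnot(length(person) == 1, length(entity) == 1)
  if (length(codes) == 0) stop("'codes' must be non-empty")
  sub <- events$code[events$person_id == person & events$entity == entity]
  counts <- as.integer(table(factor(sub, levels = codes)))
  if (binary) counts <- as.integer(counts > 0)
  setNames(counts, codes)
}

# Sparse persons x codes occurrence matrix for one entity; rows follow
# `persons`, columns follow `codes`. Used by the vectorised scoring path.
count_matrix <- function(events, persons, entity, codes, binary = FALSE) {
  sub <- events[events$entity == entity &
                  events$person_id %in% persons &
                  events$code %in% codes, c("person_id", "code")]
  i <- match(sub$person_id, persons)
  j <- match(sub$code, codes)
  m <- Matrix::sparseMatrix(i = i, j = j, x = rep(1, length(i)),
                            dims = c(length(persons), length(codes)),
                            dimnames = list(persons, codes))
  if (binary) m@x[] <- 1 * (m@x > 0) # after sparseMatrix sums duplicates
  if (binary) m <- Matrix::drop0(m)
  m
}

#' Read / write coded events as CSV
#'
#' Delimited text with header `person_id, entity, code, event_date, value,
#' quantity`; UTF-8, ISO-8601 dates, empty string for missing. Writing then
#' reading is an identity on the event table.
#'
#' @param path File path.
#' @return `read_events()` returns the event tibble.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- count.fields(path, sep = ",", quote = "\"")
  if (length(nf) > 0 && any(nf != nf[1])) {
    bad_line <- which(nf != nf[1])[1]
    stop("malformed row in ", path, " at line ", bad_line,
         ": expected ", nf[1], " fields, found ", nf[bad_line])
  }
  df <- read.csv(path, colClasses = c(person_id = "character",
                                      entity = "character",
                                      code = "character",
                                      event_date = "character",
                                      value = "numeric",
                                      quantity = "numeric"),
                 na.strings = "", fileEncoding = "UTF-8")
  df$event_date <- as.Date(df$event_date)
  df$code[is.na(df$code)] <- ""
  validate_events(df, allow_incomplete = TRUE)
}

#' @rdname read_events
#' @param events Event table to write.
#' @export
write_events <- function(events, path) {
  events <- validate_events(events, allow_incomplete = TRUE)
  out <- events
  out$event_date <- format(out$event_date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write recruitment labels as CSV
#'
#' Labels carry, per person and project, the recruitment outcome
#' (`recruited`, 0/1 gold standard) and whether a database query over the
#' study's inclusion/exclusion criteria identified the person
#' (`db_identified`, 0/1).
#'
#' @param path File path.
#' @return `read_labels()` returns a tibble with columns `person_id`,
#'   `project_id`, `recruited`, `db_identified`.
#' @export
read_labels <- function(path) {
  df <- read.csv(path, colClasses = c(person_id = "character",
                                      project_id = "character",
                                      recruited = "integer",
                                      db_identified = "integer"),
                 fileEncoding = "UTF-8")
  stopifnot(all(df$recruited %in% 0:1), all(df$db_identified %in% 0:1))
  as_tibble(df)
}

#' @rdname read_labels
#' @param labels Label table to write.
#' @export
write_labels <- function(labels, path) {
  write.csv(labels, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
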