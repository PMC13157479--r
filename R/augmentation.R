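# Expert-in-the-loop catalog augmentation: whenever retrieval returns a
# wrong code for a surface form, the reviewer logs a correction; applied
# corrections become local-layer synonyms, so subsequent exact-tier
# lookup of that surface returns the correct code. Phenotypes missing
# from the ontology altogether are logged with a MISSING marker and
# exported for upstream submission.

CORRECTION_COLUMNS <- c("surface", "predicted_code", "correct_code",
                        "proposed_label", "reviewer", "timestamp", "corpus")

#' An empty correction log
#'
#' @return Zero-row correction tibble.
#' @export
correction_log <- function() {
  tibble::tibble(
    surface = character(), predicted_code = character(),
    correct_code = character(), proposed_label = character(),
    reviewer = character(), timestamp = character(), corpus = character()
  )
}

#' Log one retrieval correction
#'
#' `correct = NA` marks a phenotype MISSING from the ontology; a
#' `proposed_label` is then required. Entries whose predicted and
#' correct codes coincide are no-ops and rejected. Duplicate (surface,
#' correct) pairs are deduplicated, so logging the same correction twice
#' leaves the log unchanged.
#'
#' @param log A correction tibble (see [correction_log()]).
#' @param surface The segment surface form that was misretrieved.
#' @param predicted The code retrieval returned (`NA` if none, e.g.
#'   under exact-tier-only matching).
#' @param correct The correct code, or `NA` for MISSING.
#' @param proposed_label Proposed label for MISSING phenotypes.
#' @param reviewer Free-text reviewer tag.
#' @param corpus Provenance tag of the corpus the miss was observed on
#'   (`"training"` by default; corrections tagged `"validation"` are
#'   refused at apply time by the CLI to prevent leakage).
#' @param timestamp ISO-8601 string; defaults to the current UTC time.
#' @return The updated correction tibble.
#' @export
log_correction <- function(log, surface, predicted, correct,
                           proposed_label = NA_character_,
                           reviewer = NA_character_, corpus = "training",
                           timestamp = NULL) {
  surface <- stringr::str_squish(stringi::stri_trans_nfc(surface))
  if (!nzchar(surface)) stop("empty surface form", call. = FALSE)
  predicted <- if (is.na(predicted)) NA_character_ else canonicalize_hpo(predicted)
  missing_term <- is.na(correct)
  correct <- if (missing_term) NA_character_ else canonicalize_hpo(correct)
  if (missing_term && is.na(proposed_label)) {
    stop("MISSING entries require a proposed_label", call. = FALSE)
  }
  if (!missing_term && !is.na(predicted) && identical(predicted, correct)) {
    stop("predicted and correct code are both ", hpo_curie(correct),
         ": the entry is a no-op", call. = FALSE)
  }
  key_surface <- normalize_surface(surface)
  dup <- normalize_surface(log$surface) == key_surface &
    (ifelse(is.na(log$correct_code), "<missing>", log$correct_code) ==
       ifelse(is.na(correct), "<missing>", correct))
  if (any(dup)) return(log)
  dplyr::bind_rows(log, tibble::tibble(
    surface = surface, predicted_code = predicted, correct_code = correct,
    proposed_label = proposed_label, reviewer = reviewer,
    timestamp = timestamp %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    corpus = corpus
  ))
}

#' Apply logged corrections to a catalog
#'
#' Every non-MISSING entry is added to the local layer via
#' [add_synonym()]; MISSING entries are left untouched. Application is
#' all-or-nothing: conflicting corrections (one surface, two different
#' correct codes, including conflicts with the existing local layer)
#' abort before anything is applied.
#'
#' @param catalog An `hpo_catalog`.
#' @param log A correction tibble.
#' @return List: `catalog` (updated), `n_applied` (count of entries that
#'   changed the catalog; re-applying the same log yields 0).
#' @export
apply_corrections <- function(catalog, log) {
  stopifnot(inherits(catalog, "hpo_catalog"))
  todo <- log[!is.na(log$correct_code), ]
  if (nrow(todo) == 0) return(list(catalog = catalog, n_applied = 0L))
  key <- normalize_surface(todo$surface)
  agg <- tapply(todo$correct_code, key, function(z) length(unique(z)))
  clash <- names(agg)[agg > 1]
  local <- catalog[catalog$layer == "local", ]
  hit <- match(key, local$norm)
  conflict_existing <- !is.na(hit) & local$code[ifelse(is.na(hit), 1L, hit)] !=
    todo$correct_code
  if (length(clash) > 0 || any(conflict_existing)) {
    msgs <- c(
      if (length(clash) > 0)
        sprintf("conflicting corrections for '%s'", clash),
      if (any(conflict_existing))
        sprintf("'%s' already maps to %s in the local layer (correction says %s)",
                todo$surface[conflict_existing],
                local$code[hit[conflict_existing]],
                todo$correct_code[conflict_existing])
    )
    stop("corrections not applied (all-or-nothing): ",
         paste(msgs, collapse = "; "), call. = FALSE)
  }
  n_applied <- 0L
  for (i in seq_len(nrow(todo))) {
    before <- nrow(catalog)
    catalog <- add_synonym(catalog, todo$surface[[i]], todo$correct_code[[i]])
    if (nrow(catalog) > before) n_applied <- n_applied + 1L
  }
  list(catalog = catalog, n_applied = n_applied)
}

#' Export phenotypes missing from the ontology
#'
#' TSV of the MISSING entries (surface, proposed label, reviewer,
#' timestamp), stable-sorted by surface, ready for upstream submission.
#' [read_missing_terms()] reads the file back.
#'
#' @param log A correction tibble.
#' @param path Output path.
#' @export
export_missing_terms <- function(log, path) {
  miss <- log[is.na(log$correct_code), ]
  if (nrow(miss) > 0) miss <- miss[order(miss$surface, method = "radix"), ]
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(c("surface\tproposed_label\treviewer\ttimestamp",
               if (nrow(miss) > 0)
                 paste(miss$surface, miss$proposed_label, miss$reviewer,
                       miss$timestamp, sep = "\t")),
             con, sep = "\n")
  invisible(path)
}

#' @rdname export_missing_terms
#' @export
read_missing_terms <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) <= 1) {
    return(tibble::tibble(surface = character(), proposed_label = character(),
                          reviewer = character(), timestamp = character()))
  }
  m <- do.call(rbind, strsplit(lines[-1], "\t", fixed = TRUE))
  tibble::tibble(surface = m[, 1], proposed_label = m[, 2],
                 reviewer = m[, 3], timestamp = m[, 4])
}

#' Read / write a correction log as JSONL
#'
#' Append-only log format: one JSON object per line with the correction
#' columns; `null` codes encode the MISSING marker.
#'
#' @param log A correction tibble.
#' @param path File path.
#' @export
write_corrections <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i) {
    jsonlite::toJSON(lapply(as.list(log[i, ]), function(v)
      if (is.na(v)) NULL else v), auto_unbox = TRUE, null = "null")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_corrections
#' @export
read_corrections <- function(path) {
  if (!file.exists(path)) stop("correction log not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(stringr::str_trim(lines))]
  log <- correction_log()
  for (i in seq_along(lines)) {
    obj <- jsonlite::fromJSON(lines[[i]])
    log <- log_correction(
      log, obj$surface,
      predicted = obj$predicted_code %||% NA_character_,
      correct = obj$correct_code %||% NA_character_,
      proposed_label = obj$proposed_label %||% NA_character_,
      reviewer = obj$reviewer %||% NA_character_,
      corpus = obj$corpus %||% "training",
      timestamp = obj$timestamp %||% NA_character_
    )
  }
  log
}
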