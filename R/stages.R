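# Pre-processing stages: translation -> segmentation -> exclusion and
# negation. Stage errors skip the affected record (collected in the
# result's "skipped" table) rather than aborting the corpus.

RECORD_COLUMNS <- c("record_id", "anterior_text", "posterior_text", "language")

.empty_skipped <- function() {
  tibble::tibble(record_id = character(), stage = character(),
                 message = character())
}

#' Construct a clinical-record table
#'
#' @param record_id Character vector of unique identifiers.
#' @param anterior_text,posterior_text Free-text fields for the two eye
#'   segments (`""` when absent).
#' @param language `"de"` or `"en"` per record.
#' @return Tibble with the four record columns.
#' @export
clinical_records <- function(record_id, anterior_text = "", posterior_text = "",
                             language = "de") {
  df <- tibble::tibble(
    record_id = as.character(record_id),
    anterior_text = as.character(anterior_text),
    posterior_text = as.character(posterior_text),
    language = as.character(language)
  )
  .validate_records(df)
}

.validate_records <- function(df) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(RECORD_COLUMNS, names(df))
  if ("language" %in% missing_cols) {
    df$language <- "de"
    missing_cols <- setdiff(missing_cols, "language")
  }
  for (col in intersect(missing_cols, c("anterior_text", "posterior_text"))) {
    df[[col]] <- ""
    missing_cols <- setdiff(missing_cols, col)
  }
  if (length(missing_cols) > 0) {
    stop("record table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$record_id)) {
    stop("duplicate record_id(s): ",
         paste(unique(df$record_id[duplicated(df$record_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$language), c("de", "en"))
  if (length(bad) > 0) {
    stop("unsupported language(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  df$anterior_text[is.na(df$anterior_text)] <- ""
  df$posterior_text[is.na(df$posterior_text)] <- ""
  df[RECORD_COLUMNS]
}

#' Read / write clinical records
#'
#' JSONL (one object per line with keys `record_id`, `anterior_text`,
#' `posterior_text`, `language`) or CSV with the same columns, selected
#' by file extension.
#'
#' @param path File path (`.jsonl`/`.ndjson` or `.csv`).
#' @return `read_records()`: a validated record tibble.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("record file not found: ", path, call. = FALSE)
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(stringr::str_trim(lines))]
    if (length(lines) == 0) {
      return(clinical_records(character(0), character(0), character(0), character(0)))
    }
    rows <- lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) {
        stop("malformed JSONL at line ", i, " of ", basename(path), ": ",
             conditionMessage(e), call. = FALSE)
      })
      tibble::tibble(
        record_id = as.character(obj$record_id %||% NA_character_),
        anterior_text = as.character(obj$anterior_text %||% ""),
        posterior_text = as.character(obj$posterior_text %||% ""),
        language = as.character(obj$language %||% "de")
      )
    })
    df <- dplyr::bind_rows(rows)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  .validate_records(df)
}

#' @rdname read_records
#' @param records A record tibble.
#' @export
write_records <- function(records, path) {
  records <- .validate_records(records)
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      jsonlite::toJSON(as.list(records[i, ]), auto_unbox = TRUE)
    }, character(1))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
  } else {
    readr::write_csv(records, path, progress = FALSE)
  }
  invisible(path)
}

#' Translate records to English
#'
#' Records with `language == "en"` are returned unchanged; German
#' records have both text fields replaced by the backend's translation
#' and `language` set to `"en"`. A backend failure skips the record (it
#' is dropped from the returned table and listed in the `skipped`
#' attribute with the error message).
#'
#' @param records Record tibble.
#' @param backend Generation backend (default: packaged rule backend).
#' @param prompt Optional prompt template (see [read_prompt_template()]).
#' @return Translated record tibble with a `skipped` attribute (tibble
#'   of `record_id`, `stage`, `message`).
#' @export
translate_records <- function(records, backend = rule_generation_backend(),
                              prompt = NULL) {
  records <- .validate_records(records)
  skipped <- list()
  keep <- rep(TRUE, nrow(records))
  de <- which(records$language == "de")
  if (length(de) > 0) {
    # fast path: translate all German records in one vectorized call;
    # on backend failure fall back to per-record calls so only the
    # failing records are skipped
    batch <- tryCatch(list(
      a = backend_translate(backend, records$anterior_text[de], prompt),
      p = backend_translate(backend, records$posterior_text[de], prompt)
    ), error = function(e) NULL)
    if (!is.null(batch) && length(batch$a) == length(de) &&
        length(batch$p) == length(de)) {
      records$anterior_text[de] <- batch$a
      records$posterior_text[de] <- batch$p
      records$language[de] <- "en"
    } else {
      for (i in de) {
        res <- tryCatch({
          list(a = backend_translate(backend, records$anterior_text[[i]], prompt),
               p = backend_translate(backend, records$posterior_text[[i]], prompt))
        }, error = function(e) e)
        if (inherits(res, "error")) {
          keep[[i]] <- FALSE
          skipped[[length(skipped) + 1L]] <- tibble::tibble(
            record_id = records$record_id[[i]], stage = "translate",
            message = conditionMessage(res))
          next
        }
        records$anterior_text[[i]] <- res$a
        records$posterior_text[[i]] <- res$p
        records$language[[i]] <- "en"
      }
    }
  }
  out <- records[keep, ]
  sk <- dplyr::bind_rows(skipped)
  attr(out, "skipped") <- if (nrow(sk) == 0) .empty_skipped() else sk
  out
}

#' Segment a free-text field into discrete findings
#'
#' @param text One free-text field.
#' @param scope `"anterior"` or `"posterior"`.
#' @param backend Generation backend.
#' @param prompt Optional prompt template.
#' @param record_id Identifier attached to the produced segments.
#' @return Tibble of segments: `record_id`, `scope`, `ordinal`
#'   (consecutive from 0), `text`; zero rows for empty input. A warning
#'   is raised when the backend's segments lose more than half of the
#'   input's non-whitespace characters.
#' @export
segment_text <- function(text, scope, backend = rule_generation_backend(),
                         prompt = NULL, record_id = NA_character_) {
  scope <- match.arg(scope, c("anterior", "posterior"))
  segs <- backend_segment(backend, text, prompt)[[1]]
  segs <- segs[nzchar(stringr::str_squish(segs))]
  n_in <- nchar(gsub("\\s", "", text %||% ""))
  n_out <- sum(nchar(gsub("\\s", "", segs)))
  if (n_in > 0 && n_out < 0.5 * n_in) {
    warning("segmentation of record ", record_id, " (", scope, ") lost ",
            n_in - n_out, " of ", n_in, " characters", call. = FALSE)
  }
  tibble::tibble(
    record_id = rep(record_id, length(segs)),
    scope = rep(scope, length(segs)),
    ordinal = seq_along(segs) - 1L,
    text = segs
  )
}

#' Classify segments as pathological, normal or negated
#'
#' @param segments Segment tibble (from [segment_text()]).
#' @param backend Generation backend.
#' @param prompt Optional prompt template.
#' @return The segment tibble with a `status` column.
#' @export
classify_segments <- function(segments, backend = rule_generation_backend(),
                              prompt = NULL) {
  segments$status <- if (nrow(segments) == 0) character(0) else
    backend_classify(backend, segments$text, prompt)
  segments
}

#' Run translation, segmentation and classification; keep pathology
#'
#' Applies the full pre-processing cascade per record and returns only
#' the segments classified as pathological, tagged with record id and
#' scope. Per-record stage errors are collected in the `skipped`
#' attribute, not raised.
#'
#' @param records Record tibble.
#' @param backend Generation backend.
#' @param prompts Optional named list of prompt templates
#'   (`translate`, `segment`, `classify`).
#' @return Segment tibble (`record_id`, `scope`, `ordinal`, `text`,
#'   `status == "pathological"`) with a `skipped` attribute.
#' @export
pathological_segments <- function(records, backend = rule_generation_backend(),
                                  prompts = list()) {
  all_segments <- extract_segments(records, backend, prompts)
  out <- all_segments[all_segments$status == "pathological", ]
  attr(out, "skipped") <- attr(all_segments, "skipped")
  out
}

#' @rdname pathological_segments
#' @export
extract_segments <- function(records, backend = rule_generation_backend(),
                             prompts = list()) {
  translated <- translate_records(records, backend, prompts$translate)
  skipped <- attr(translated, "skipped")
  keep_err <- list()
  acc_id <- list(); acc_scope <- list(); acc_ord <- list(); acc_text <- list()
  for (i in seq_len(nrow(translated))) {
    res <- tryCatch({
      a <- backend_segment(backend, translated$anterior_text[[i]],
                           prompts$segment)[[1]]
      p <- backend_segment(backend, translated$posterior_text[[i]],
                           prompts$segment)[[1]]
      a <- a[nzchar(stringr::str_squish(a))]
      p <- p[nzchar(stringr::str_squish(p))]
      list(a = a, p = p)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      keep_err[[length(keep_err) + 1L]] <- tibble::tibble(
        record_id = translated$record_id[[i]], stage = "segment",
        message = conditionMessage(res))
      next
    }
    .warn_segment_loss(translated$anterior_text[[i]], res$a,
                       translated$record_id[[i]], "anterior")
    .warn_segment_loss(translated$posterior_text[[i]], res$p,
                       translated$record_id[[i]], "posterior")
    n <- length(res$a) + length(res$p)
    if (n == 0) next
    acc_id[[length(acc_id) + 1L]] <- rep(translated$record_id[[i]], n)
    acc_scope[[length(acc_scope) + 1L]] <-
      c(rep("anterior", length(res$a)), rep("posterior", length(res$p)))
    acc_ord[[length(acc_ord) + 1L]] <-
      c(seq_along(res$a) - 1L, seq_along(res$p) - 1L)
    acc_text[[length(acc_text) + 1L]] <- c(res$a, res$p)
  }
  out <- tibble::tibble(
    record_id = unlist(acc_id) %||% character(0),
    scope = unlist(acc_scope) %||% character(0),
    ordinal = as.integer(unlist(acc_ord) %||% integer(0)),
    text = unlist(acc_text) %||% character(0)
  )
  out <- classify_segments(out, backend, prompts$classify)
  sk <- dplyr::bind_rows(c(list(skipped), keep_err))
  attr(out, "skipped") <- if (nrow(sk) == 0) .empty_skipped() else sk
  out
}

.warn_segment_loss <- function(text, segs, record_id, scope) {
  n_in <- nchar(gsub("\\s", "", text %||% ""))
  if (n_in == 0) return(invisible())
  n_out <- sum(nchar(gsub("\\s", "", segs)))
  if (n_out < 0.5 * n_in) {
    warning("segmentation of record ", record_id, " (", scope, ") lost ",
            n_in - n_out, " of ", n_in, " characters", call. = FALSE)
  }
  invisible()
}
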