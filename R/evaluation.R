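# Validation harness: per-record comparison of predicted vs
# ground-truth HPO code sets, with Jaccard, precision, recall and F1,
# aggregated both as medians of per-record values (the headline
# presentation) and as micro-pooled counts across the corpus.

#' Per-record set-comparison metrics
#'
#' With `tp = |pred n truth|`, `fp = |pred \\ truth|`,
#' `fn = |truth \\ pred|`:
#' `jaccard = tp / (tp + fp + fn)`, `precision = tp / (tp + fp)`,
#' `recall = tp / (tp + fn)`, `f1 = 2 tp / (2 tp + fp + fn)`; the
#' identity `jaccard = f1 / (2 - f1)` holds whenever both are defined.
#' Degenerate cases: both sets empty -> all metrics 1.0 (a record with
#' no pathology, correctly predicted as such); exactly one side empty ->
#' all metrics 0.
#'
#' @param pred,truth Character vectors of HPO codes (any accepted
#'   spelling; duplicates collapse; the ignore sentinel is an input
#'   error).
#' @return One-row tibble: `tp`, `fp`, `fn`, `jaccard`, `precision`,
#'   `recall`, `f1`.
#' @export
record_metrics <- function(pred, truth) {
  pred <- unique(canonicalize_hpo(pred))
  truth <- unique(canonicalize_hpo(truth))
  if (any(pred == HPO_IGNORE) || any(truth == HPO_IGNORE)) {
    stop("the ignore sentinel is not a valid annotation code", call. = FALSE)
  }
  tp <- length(intersect(pred, truth))
  fp <- length(setdiff(pred, truth))
  fn <- length(setdiff(truth, pred))
  if (tp + fp + fn == 0) {
    return(tibble::tibble(tp = 0L, fp = 0L, fn = 0L, jaccard = 1,
                          precision = 1, recall = 1, f1 = 1))
  }
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    jaccard = tp / (tp + fp + fn),
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0,
    f1 = 2 * tp / (2 * tp + fp + fn)
  )
}

#' Evaluate a corpus of predictions against ground truth
#'
#' Records present on only one side are treated as an empty set on the
#' other side (with a warning). Medians are the standard order-statistic
#' median (mean of the middle two for even n).
#'
#' @param predictions,truths Named lists: record_id -> character vector
#'   of codes.
#' @return An `hpo_eval_report`: list with `per_record` (tibble) and
#'   `summary` (medians of the four metrics, mean and total predicted
#'   and truth terms per record, micro-pooled precision/recall/F1).
#' @export
evaluate_corpus <- function(predictions, truths) {
  ids <- union(names(predictions), names(truths))
  if (length(ids) == 0) stop("empty corpus: no records to evaluate", call. = FALSE)
  only_pred <- setdiff(names(predictions), names(truths))
  only_truth <- setdiff(names(truths), names(predictions))
  if (length(only_pred) > 0) {
    warning(length(only_pred), " record(s) lack ground truth; treated as empty",
            call. = FALSE)
  }
  if (length(only_truth) > 0) {
    warning(length(only_truth), " record(s) lack predictions; treated as empty",
            call. = FALSE)
  }
  ids <- sort(ids)
  per <- dplyr::bind_rows(lapply(ids, function(id) {
    m <- record_metrics(predictions[[id]] %||% character(0),
                        truths[[id]] %||% character(0))
    m$record_id <- id
    m$n_pred <- m$tp + m$fp
    m$n_truth <- m$tp + m$fn
    m
  }))
  per <- per[, c("record_id", "n_pred", "n_truth", "tp", "fp", "fn",
                 "jaccard", "precision", "recall", "f1")]
  tp <- sum(per$tp); fp <- sum(per$fp); fn <- sum(per$fn)
  micro_p <- if (tp + fp > 0) tp / (tp + fp) else 1
  micro_r <- if (tp + fn > 0) tp / (tp + fn) else 1
  micro_f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1
  summary <- list(
    n_records = length(ids),
    mean_pred_terms = mean(per$n_pred),
    mean_truth_terms = mean(per$n_truth),
    total_pred_terms = sum(per$n_pred),
    total_truth_terms = sum(per$n_truth),
    median_jaccard = stats::median(per$jaccard),
    median_precision = stats::median(per$precision),
    median_recall = stats::median(per$recall),
    median_f1 = stats::median(per$f1),
    micro_precision = micro_p,
    micro_recall = micro_r,
    micro_f1 = micro_f1
  )
  structure(list(per_record = per, summary = summary), class = "hpo_eval_report")
}

#' @export
print.hpo_eval_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<hpo_eval_report> %d records\n", s$n_records))
  cat(sprintf("  terms/record (mean): predicted %.2f, truth %.2f (totals %d / %d)\n",
              s$mean_pred_terms, s$mean_truth_terms,
              s$total_pred_terms, s$total_truth_terms))
  cat(sprintf("  medians: Jaccard %.2f, precision %.2f, recall %.2f, F1 %.2f\n",
              s$median_jaccard, s$median_precision, s$median_recall, s$median_f1))
  cat(sprintf("  micro:   precision %.2f, recall %.2f, F1 %.2f\n",
              s$micro_precision, s$micro_recall, s$micro_f1))
  invisible(x)
}

#' Render an evaluation report to disk
#'
#' Writes `report.json` (the full machine-readable report) and
#' `report.md` (a Markdown summary table: mean terms per record, total
#' identified terms, and the median Jaccard / precision / recall / F1,
#' formatted to two decimals, plus the micro-pooled row).
#'
#' @param report An `hpo_eval_report`.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
render_report <- function(report, dir) {
  stopifnot(inherits(report, "hpo_eval_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  md_path <- file.path(dir, "report.md")
  jsonlite::write_json(
    list(summary = report$summary, per_record = report$per_record),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  s <- report$summary
  f2 <- function(v) sprintf("%.2f", v)
  md <- c(
    sprintf("# Validation report (n = %d)", s$n_records),
    "",
    "| Metric | Pipeline | Ground truth |",
    "| --- | --- | --- |",
    sprintf("| HPO terms per medical record (mean) | %s | %s |",
            f2(s$mean_pred_terms), f2(s$mean_truth_terms)),
    sprintf("| Identified HPO terms in total | %d | %d |",
            s$total_pred_terms, s$total_truth_terms),
    sprintf("| Jaccard similarity: median | %s | |", f2(s$median_jaccard)),
    sprintf("| Precision: median | %s | |", f2(s$median_precision)),
    sprintf("| Recall: median | %s | |", f2(s$median_recall)),
    sprintf("| F1 score: median | %s | |", f2(s$median_f1)),
    sprintf("| Precision / recall / F1 (micro-pooled) | %s / %s / %s | |",
            f2(s$micro_precision), f2(s$micro_recall), f2(s$micro_f1))
  )
  con <- file(md_path, open = "wb")
  writeLines(md, con, sep = "\n")
  close(con)
  invisible(c(json = json_path, markdown = md_path))
}

#' Read / write ground-truth (or prediction) code sets
#'
#' JSONL with one object per record: `record_id` and `codes` (array of
#' HPO codes in any accepted spelling).
#'
#' @param path File path.
#' @return Named list: record_id -> sorted character vector of codes.
#' @export
read_code_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(stringr::str_trim(lines))]
  out <- list()
  for (ln in lines) {
    obj <- jsonlite::fromJSON(ln)
    codes <- unlist(obj$codes, use.names = FALSE)
    out[[as.character(obj$record_id)]] <-
      if (length(codes) == 0) character(0) else sort(unique(canonicalize_hpo(codes)))
  }
  out
}

#' @rdname read_code_sets
#' @param sets Named list: record_id -> character vector of codes.
#' @export
write_code_sets <- function(sets, path) {
  ids <- names(sets)
  lines <- vapply(ids, function(id) {
    jsonlite::toJSON(list(record_id = id, codes = as.character(sets[[id]])),
                     auto_unbox = TRUE)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
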