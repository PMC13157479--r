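# Mapping of pathological findings to HPO codes: an exact-match tier
# over normalized surface forms, then K = 1 cosine nearest-neighbour
# search over the embedded catalog. There is no similarity threshold by
# default — every finding is assigned its single closest catalog entry,
# and the similarity is recorded so callers can post-filter.

#' Build an embedding index over a catalog
#'
#' Every distinct normalized surface form of the catalog (labels and
#' synonyms, both layers, ignore-sentinel entries included) is embedded
#' once. Entries appear in the catalog's stable sort order (code, then
#' surface); a surface present in both layers resolves to its
#' local-layer code before embedding.
#'
#' @param catalog A non-empty `hpo_catalog`.
#' @param backend An embedding backend (default [hash_embedding_backend()]).
#' @return An object of class `hpo_index` with fields `entries`
#'   (tibble: `norm`, `surface`, `code`, `layer`, `scope`), `vectors`
#'   (unit-row matrix), `backend`, `dim`, `checksum`.
#' @export
build_index <- function(catalog, backend = hash_embedding_backend()) {
  stopifnot(inherits(catalog, "hpo_catalog"))
  if (nrow(catalog) == 0) stop("cannot build an index over an empty catalog",
                               call. = FALSE)
  entries <- surface_index(catalog)
  vectors <- embed_texts(backend, entries$norm)
  if (!is.matrix(vectors) || nrow(vectors) != nrow(entries)) {
    stop("embedding backend returned a malformed matrix", call. = FALSE)
  }
  lens <- sqrt(rowSums(vectors^2))
  if (any(lens == 0)) {
    stop("embedding backend produced a zero-length vector for surface '",
         entries$surface[which(lens == 0)[1]], "'", call. = FALSE)
  }
  vectors <- vectors / lens # enforce unit rows so dot product = cosine
  structure(
    list(entries = entries, vectors = vectors, backend = backend,
         dim = ncol(vectors), checksum = catalog_checksum(catalog)),
    class = "hpo_index"
  )
}

#' @export
print.hpo_index <- function(x, ...) {
  cat(sprintf("<hpo_index> %d surfaces, dim %d, backend %s, catalog %s\n",
              nrow(x$entries), x$dim, x$backend$id, x$checksum))
  invisible(x)
}

#' Map one finding to its single closest HPO code (K = 1)
#'
#' Tier 1 (exact): if the normalized segment text equals a catalog
#' surface, that surface's code is returned with similarity 1.0. Tier 2
#' (embedding): cosine nearest neighbour over all index entries, K = 1,
#' no threshold. Exact cosine ties break to the local layer first, then
#' the lexicographically smallest code. A winning ignore-sentinel entry
#' is an ignore verdict: downstream annotation emits nothing for the
#' segment.
#'
#' @param text The finding text (one string).
#' @param index An `hpo_index`.
#' @param use_embedding If `FALSE`, only the exact tier runs and
#'   findings without an exact match return `NULL` (no match).
#' @param min_similarity Optional post-filter: embedding-tier matches
#'   below this cosine return `NULL`. Default `NULL` (off), matching
#'   the unconditional K = 1 assignment.
#' @return A one-row tibble (`code`, `similarity`, `tier`,
#'   `matched_surface`) — `code` may be the ignore sentinel — or `NULL`
#'   when no match is produced.
#' @export
map_segment <- function(text, index, use_embedding = TRUE, min_similarity = NULL) {
  stopifnot(inherits(index, "hpo_index"))
  if (nrow(index$entries) == 0) stop("empty index", call. = FALSE)
  n <- normalize_surface(text)
  hit <- match(n, index$entries$norm)
  if (!is.na(hit)) {
    return(tibble::tibble(
      code = index$entries$code[[hit]], similarity = 1.0, tier = "exact",
      matched_surface = index$entries$surface[[hit]]
    ))
  }
  if (!use_embedding) return(NULL)
  q <- embed_texts(index$backend, n)[1, ]
  sims <- as.vector(index$vectors %*% q)
  layer_rank <- ifelse(index$entries$layer == "local", 0L, 1L)
  best <- order(-sims, layer_rank, index$entries$code, method = "radix")[1]
  if (!is.null(min_similarity) && sims[[best]] < min_similarity) return(NULL)
  tibble::tibble(
    code = index$entries$code[[best]], similarity = sims[[best]],
    tier = "embedding", matched_surface = index$entries$surface[[best]]
  )
}

.empty_annotations <- function() {
  tibble::tibble(record_id = character(), scope = character(),
                 text = character(), code = character(),
                 similarity = numeric(), tier = character(),
                 matched_surface = character())
}

# vectorized mapping of a segment table; semantics identical to calling
# map_segment() per row
.map_segment_table <- function(segments, index, use_embedding, min_similarity) {
  n_seg <- nrow(segments)
  if (n_seg == 0) return(.empty_annotations())
  norm <- normalize_surface(segments$text)
  hit <- match(norm, index$entries$norm)
  code <- index$entries$code[hit]
  matched <- index$entries$surface[hit]
  sim <- ifelse(is.na(hit), NA_real_, 1.0)
  tier <- ifelse(is.na(hit), NA_character_, "exact")
  miss <- which(is.na(hit))
  if (use_embedding && length(miss) > 0) {
    q <- embed_texts(index$backend, norm[miss])
    sims <- q %*% t(index$vectors) # rows: queries, cols: entries
    layer_rank <- ifelse(index$entries$layer == "local", 0L, 1L)
    for (j in seq_along(miss)) {
      s <- sims[j, ]
      best <- order(-s, layer_rank, index$entries$code, method = "radix")[1]
      if (!is.null(min_similarity) && s[[best]] < min_similarity) next
      i <- miss[[j]]
      code[[i]] <- index$entries$code[[best]]
      matched[[i]] <- index$entries$surface[[best]]
      sim[[i]] <- s[[best]]
      tier[[i]] <- "embedding"
    }
  }
  keep <- !is.na(code) & code != HPO_IGNORE
  tibble::tibble(
    record_id = segments$record_id[keep], scope = segments$scope[keep],
    text = segments$text[keep], code = code[keep], similarity = sim[keep],
    tier = tier[keep], matched_surface = matched[keep]
  )
}

#' Annotate a whole corpus of records
#'
#' Runs the pre-processing cascade ([pathological_segments()]) and maps
#' every pathological segment. The record-level prediction is the SET of
#' distinct codes (duplicates collapse; Jaccard and friends are set
#' measures); the annotation table preserves per-segment provenance.
#' Segments whose best match is the ignore sentinel produce no
#' annotation, as do unmatched segments under `use_embedding = FALSE`.
#'
#' @param records Record tibble.
#' @param index An `hpo_index`.
#' @param backend Generation backend for the pre-processing stages.
#' @param use_embedding,min_similarity See [map_segment()].
#' @param prompts Optional prompt templates (see [pathological_segments()]).
#' @return List: `annotations` (tibble), `sets` (named list record_id ->
#'   sorted character vector of codes; every input record present, empty
#'   vectors for records with no annotation), `skipped` (tibble of
#'   per-record stage errors).
#' @export
annotate_corpus <- function(records, index, backend = rule_generation_backend(),
                            use_embedding = TRUE, min_similarity = NULL,
                            prompts = list()) {
  records <- .validate_records(records)
  segs <- pathological_segments(records, backend, prompts)
  skipped <- attr(segs, "skipped")
  ann <- .map_segment_table(segs, index, use_embedding, min_similarity)
  processed <- setdiff(records$record_id,
                       if (is.null(skipped) || nrow(skipped) == 0) character(0)
                       else skipped$record_id)
  sets <- lapply(processed, function(id) {
    sort(unique(ann$code[ann$record_id == id]))
  })
  names(sets) <- processed
  list(annotations = ann, sets = sets,
       skipped = skipped %||% tibble::tibble(record_id = character(),
                                             stage = character(),
                                             message = character()))
}

#' Annotate a single record
#'
#' @inheritParams annotate_corpus
#' @param record A one-row record tibble.
#' @return List: `codes` (sorted distinct codes, sentinel never
#'   included), `annotations` (per-segment detail tibble).
#' @export
annotate_record <- function(record, index, backend = rule_generation_backend(),
                            use_embedding = TRUE, min_similarity = NULL,
                            prompts = list()) {
  res <- annotate_corpus(record, index, backend, use_embedding,
                         min_similarity, prompts)
  codes <- if (length(res$sets) > 0) res$sets[[1]] else character(0)
  list(codes = codes, annotations = res$annotations)
}

#' Write annotations as JSONL
#'
#' One object per annotation: `record_id`, `scope`, `text`, `hpo_id`
#' (CURIE form), `similarity`, `tier`, `matched_surface`.
#'
#' @param annotations Annotation tibble from [annotate_corpus()].
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  lines <- vapply(seq_len(nrow(annotations)), function(i) {
    jsonlite::toJSON(list(
      record_id = annotations$record_id[[i]], scope = annotations$scope[[i]],
      text = annotations$text[[i]], hpo_id = hpo_curie(annotations$code[[i]]),
      similarity = annotations$similarity[[i]], tier = annotations$tier[[i]],
      matched_surface = annotations$matched_surface[[i]]
    ), auto_unbox = TRUE, digits = NA)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Persist / reload an embedding index
#'
#' The index directory holds `entries.tsv` (surface table),
#' `vectors.tsv` (the embedding matrix, `%.17g` so floats round-trip
#' exactly) and `index.json` (backend identity and parameters,
#' dimension, and the checksum of the source catalog). `load_index()`
#' reconstructs the packaged hashing backend from the sidecar; a custom
#' backend must be passed in by the caller and must match the recorded
#' identity tag.
#'
#' @param index An `hpo_index`.
#' @param dir Directory (created if needed).
#' @export
save_index <- function(index, dir) {
  stopifnot(inherits(index, "hpo_index"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ent <- index$entries
  writeLines(
    c("norm\tsurface\tcode\tlayer\tscope",
      paste(ent$norm, ent$surface, ent$code, ent$layer, ent$scope, sep = "\t")),
    file.path(dir, "entries.tsv"), useBytes = FALSE
  )
  rows <- apply(index$vectors, 1, function(r) paste(sprintf("%.17g", r),
                                                    collapse = "\t"))
  writeLines(rows, file.path(dir, "vectors.tsv"))
  sidecar <- list(backend_id = index$backend$id, dim = index$dim,
                  n_entries = nrow(ent), checksum = index$checksum,
                  format_version = 1L)
  if (inherits(index$backend, "hash_backend")) {
    sidecar$hash_backend <- index$backend[c("dim", "ngram", "seed", "instruction")]
  }
  jsonlite::write_json(sidecar, file.path(dir, "index.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_index
#' @param dir Index directory.
#' @param backend `NULL` to reconstruct the packaged hashing backend
#'   from the sidecar, or the backend object the index was built with.
#' @export
load_index <- function(dir, backend = NULL) {
  sidecar <- jsonlite::fromJSON(file.path(dir, "index.json"))
  if (is.null(backend)) {
    hb <- sidecar$hash_backend
    if (is.null(hb)) {
      stop("index was built with a non-packaged backend (", sidecar$backend_id,
           "); pass it via `backend`", call. = FALSE)
    }
    backend <- hash_embedding_backend(hb$dim, hb$ngram, hb$seed, hb$instruction)
  }
  if (!identical(backend$id, sidecar$backend_id)) {
    stop("backend mismatch: index built with ", sidecar$backend_id,
         ", got ", backend$id, call. = FALSE)
  }
  ent_lines <- readLines(file.path(dir, "entries.tsv"), warn = FALSE,
                         encoding = "UTF-8")
  parts <- strsplit(ent_lines[-1], "\t", fixed = TRUE)
  m <- do.call(rbind, parts)
  entries <- tibble::tibble(norm = m[, 1], surface = m[, 2], code = m[, 3],
                            layer = m[, 4], scope = m[, 5])
  vec_lines <- readLines(file.path(dir, "vectors.tsv"), warn = FALSE)
  vectors <- do.call(rbind, lapply(strsplit(vec_lines, "\t", fixed = TRUE),
                                   as.numeric))
  if (nrow(vectors) != nrow(entries) || ncol(vectors) != sidecar$dim) {
    stop("corrupt index in ", dir, ": matrix shape does not match sidecar",
         call. = FALSE)
  }
  structure(
    list(entries = entries, vectors = vectors, backend = backend,
         dim = sidecar$dim, checksum = sidecar$checksum),
    class = "hpo_index"
  )
}
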