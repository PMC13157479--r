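# Layered HPO synonym catalog: a standard (ontology) layer plus a local
# (curated) layer, kept per eye segment. The catalog is a tibble of
# entries with one row per surface form; the local layer wins
# surface-form collisions against the standard layer, while collisions
# within a layer are load errors.

CATALOG_COLUMNS <- c("code", "surface", "scope", "layer", "provenance")
CATALOG_SCOPES <- c("anterior", "posterior", "both")
CATALOG_LAYERS <- c("standard", "local")
CATALOG_PROVENANCE <- c("ontology", "local-augmentation", "fixture")
CATALOG_TSV_HEADER <- "hpo_id\tsurface\tscope\tlayer\tprovenance"

#' Construct a synonym catalog from an entry table
#'
#' Validates entries, canonicalizes codes, computes normalized surfaces,
#' drops exact duplicate entries (same normalized surface, code, layer)
#' and enforces the collision rules: within one layer a normalized
#' surface may map to only one code; across layers the local layer takes
#' precedence at lookup time.
#'
#' @param entries A data frame with columns `code`, `surface`, `scope`
#'   (`"anterior"`, `"posterior"` or `"both"`), `layer` (`"standard"` or
#'   `"local"`) and `provenance` (`"ontology"`, `"local-augmentation"` or
#'   `"fixture"`). May have zero rows.
#' @return An object of class `hpo_catalog`: the validated entry tibble
#'   with an additional `norm` column.
#' @export
hpo_catalog <- function(entries) {
  entries <- tibble::as_tibble(entries)
  missing_cols <- setdiff(CATALOG_COLUMNS, names(entries))
  if (length(missing_cols) > 0) {
    stop("catalog entries lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  entries <- entries[CATALOG_COLUMNS]
  if (nrow(entries) == 0) {
    out <- tibble::tibble(
      code = character(), surface = character(), norm = character(),
      scope = character(), layer = character(), provenance = character()
    )
    class(out) <- c("hpo_catalog", class(out))
    return(out)
  }
  entries$code <- canonicalize_hpo(entries$code)
  entries$surface <- stringr::str_squish(stringi::stri_trans_nfc(entries$surface))
  if (any(!nzchar(entries$surface))) {
    stop("catalog entries contain empty surface forms", call. = FALSE)
  }
  if (any(grepl("[\t\n]", entries$surface))) {
    stop("catalog surface forms may not contain tabs or newlines", call. = FALSE)
  }
  for (col in c("scope", "layer", "provenance")) {
    allowed <- switch(col, scope = CATALOG_SCOPES, layer = CATALOG_LAYERS,
                      provenance = CATALOG_PROVENANCE)
    bad <- setdiff(unique(entries[[col]]), allowed)
    if (length(bad) > 0) {
      stop("invalid ", col, " value(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (any(entries$layer == "standard" & entries$code == HPO_IGNORE)) {
    stop("the ignore sentinel \"0\" is not allowed in the standard layer",
         call. = FALSE)
  }
  entries$norm <- normalize_surface(entries$surface)
  entries <- entries[!duplicated(entries[c("norm", "code", "layer")]), ]

  # within-layer collisions: one normalized surface -> two codes
  for (ly in unique(entries$layer)) {
    sub <- entries[entries$layer == ly, ]
    tab <- stats::aggregate(code ~ norm, data = sub,
                            FUN = function(z) length(unique(z)))
    clash <- tab$norm[tab$code > 1]
    if (length(clash) > 0) {
      offenders <- sub[sub$norm %in% clash, c("norm", "code")]
      stop("surface-form collision in ", ly, " layer: ",
           paste(sprintf("'%s' -> %s", offenders$norm, offenders$code),
                 collapse = "; "),
           call. = FALSE)
    }
  }
  entries <- entries[, c("code", "surface", "norm", "scope", "layer", "provenance")]
  class(entries) <- c("hpo_catalog", class(tibble::tibble()))
  entries
}

#' @export
print.hpo_catalog <- function(x, ...) {
  cat(sprintf(
    "<hpo_catalog> %d entries (%d local, %d standard), %d distinct codes, %d sentinel surfaces\n",
    nrow(x), sum(x$layer == "local"), sum(x$layer == "standard"),
    length(unique(x$code[x$code != HPO_IGNORE])), sum(x$code == HPO_IGNORE)
  ))
  NextMethod()
  invisible(x)
}

# Stable export/index order: by (code, surface) in the C locale.
.catalog_order <- function(catalog) {
  order(catalog$code, catalog$surface, method = "radix")
}

#' Resolved surface index of a catalog
#'
#' One row per distinct normalized surface form, with local-layer
#' entries taking precedence over standard-layer entries, in the stable
#' catalog sort order (code, then surface).
#'
#' @param catalog An `hpo_catalog`.
#' @return Tibble with columns `norm`, `surface`, `code`, `layer`, `scope`.
#' @export
surface_index <- function(catalog) {
  stopifnot(inherits(catalog, "hpo_catalog"))
  df <- tibble::as_tibble(catalog)
  if (nrow(df) == 0) {
    return(tibble::tibble(norm = character(), surface = character(),
                          code = character(), layer = character(),
                          scope = character()))
  }
  df <- df[order(match(df$layer, c("local", "standard"))), ]
  df <- df[!duplicated(df$norm), ]
  df <- df[order(df$code, df$surface, method = "radix"), ]
  df[, c("norm", "surface", "code", "layer", "scope")]
}

#' Exact-tier lookup of a surface form
#'
#' @param catalog An `hpo_catalog`.
#' @param surface Character vector of query surfaces.
#' @return Character vector of canonical codes (`NA` where the surface
#'   is unknown); local-layer mappings win collisions.
#' @export
lookup_code <- function(catalog, surface) {
  idx <- surface_index(catalog)
  idx$code[match(normalize_surface(surface), idx$norm)]
}

#' Load a subset of the HPO ontology into the standard layer
#'
#' Reads either OBO 1.2 (`[Term]` stanzas with `id`, `name`, `synonym`
#' lines) or the HPO obographs-style JSON dialect (`graphs[].nodes[]`
#' with `id`, `lbl`, `meta$synonyms[].val`). One term per concept;
#' obsolete terms are skipped; all entries get `layer = "standard"`,
#' `scope = "both"`, `provenance = "ontology"`.
#'
#' @param path Path to the ontology file.
#' @return An `hpo_catalog`.
#' @export
load_hpo_subset <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE, encoding = "UTF-8")
  if (length(first) > 0 && grepl("^\\s*\\{", first)) {
    terms <- .parse_hpo_json(path)
  } else {
    terms <- .parse_obo(path)
  }
  if (length(terms) == 0) {
    return(hpo_catalog(tibble::tibble(
      code = character(), surface = character(), scope = character(),
      layer = character(), provenance = character()
    )))
  }
  ids <- vapply(terms, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate concept id(s) in ontology: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(terms, function(t) {
    tibble::tibble(code = t$id, surface = c(t$label, t$synonyms))
  })
  entries <- dplyr::bind_rows(rows)
  entries$scope <- "both"
  entries$layer <- "standard"
  entries$provenance <- "ontology"
  hpo_catalog(entries)
}

.parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  terms <- list()
  cur <- NULL
  start_line <- NA_integer_
  flush <- function(cur, start_line) {
    if (is.null(cur)) return(NULL)
    if (isTRUE(cur$obsolete)) return(NULL)
    if (is.null(cur$id)) {
      stop("malformed OBO: [Term] at line ", start_line, " has no id", call. = FALSE)
    }
    if (is.null(cur$label)) {
      stop("malformed OBO: term ", cur$id, " (line ", start_line,
           ") has no name", call. = FALSE)
    }
    cur
  }
  for (i in seq_along(lines)) {
    ln <- stringr::str_trim(lines[[i]])
    if (ln == "[Term]") {
      done <- flush(cur, start_line)
      if (!is.null(done)) terms[[length(terms) + 1L]] <- done
      cur <- list(id = NULL, label = NULL, synonyms = character(), obsolete = FALSE)
      start_line <- i
      next
    }
    if (grepl("^\\[", ln)) { # other stanza types end the current term
      done <- flush(cur, start_line)
      if (!is.null(done)) terms[[length(terms) + 1L]] <- done
      cur <- NULL
      next
    }
    if (is.null(cur) || ln == "" || startsWith(ln, "!")) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 0) {
      stop("malformed OBO line ", i, ": '", ln, "'", call. = FALSE)
    }
    key <- m[[2]]
    val <- m[[3]]
    if (key == "id") {
      cur$id <- tryCatch(canonicalize_hpo(val), error = function(e) {
        stop("malformed OBO line ", i, ": ", conditionMessage(e), call. = FALSE)
      })
    } else if (key == "name") {
      cur$label <- val
    } else if (key == "synonym") {
      q <- regmatches(val, regexec('^"((?:[^"\\\\]|\\\\.)*)"', val))[[1]]
      if (length(q) < 2) {
        stop("malformed OBO synonym at line ", i, ": '", val, "'", call. = FALSE)
      }
      cur$synonyms <- c(cur$synonyms, gsub('\\\\(.)', "\\1", q[[2]]))
    } else if (key == "is_obsolete" && grepl("^true", val)) {
      cur$obsolete <- TRUE
    }
  }
  done <- flush(cur, start_line)
  if (!is.null(done)) terms[[length(terms) + 1L]] <- done
  terms
}

.parse_hpo_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nodes <- NULL
  if (!is.null(doc$graphs)) {
    nodes <- doc$graphs[[1]]$nodes
  } else if (!is.null(doc$terms)) {
    nodes <- doc$terms
  }
  if (is.null(nodes)) {
    stop("unrecognized ontology JSON dialect in ", path,
         " (expected 'graphs' or 'terms')", call. = FALSE)
  }
  terms <- list()
  for (k in seq_along(nodes)) {
    nd <- nodes[[k]]
    id_raw <- nd$id %||% ""
    m <- regmatches(id_raw, regexec("HP[_:]([0-9]+)", id_raw))[[1]]
    if (length(m) < 2) next # non-HP node (relations etc.)
    if (isTRUE(nd$meta$deprecated)) next
    label <- nd$lbl %||% nd$label
    if (is.null(label)) {
      stop("malformed ontology JSON: node ", k, " (", id_raw, ") has no label",
           call. = FALSE)
    }
    syns <- character()
    if (!is.null(nd$meta$synonyms)) {
      syns <- vapply(nd$meta$synonyms, function(s) s$val %||% "", character(1))
    } else if (!is.null(nd$synonyms)) {
      syns <- unlist(nd$synonyms, use.names = FALSE)
    }
    terms[[length(terms) + 1L]] <- list(
      id = canonicalize_hpo(m[[2]]), label = label,
      synonyms = syns[nzchar(syns)]
    )
  }
  terms
}

#' Load a local synonym catalog
#'
#' Two dialects are accepted: the two-column `code <TAB> surface` layout
#' of locally curated catalogs (comments with `#`, blank lines skipped;
#' `scope` must then be given), and the five-column export format
#' written by [export_catalog()] (header `hpo_id  surface  scope  layer
#' provenance`), which round-trips a full catalog.
#'
#' @param path Path to the delimited text file.
#' @param scope `"anterior"` or `"posterior"` for two-column files;
#'   ignored for the export format, which carries scope per row.
#' @param provenance Provenance tag for two-column files (default
#'   `"fixture"`).
#' @return An `hpo_catalog` with `layer = "local"` (two-column dialect).
#' @export
load_local_catalog <- function(path, scope = NULL, provenance = "fixture") {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) > 0 && identical(lines[[1]], CATALOG_TSV_HEADER)) {
    return(.load_catalog_export(lines, path))
  }
  if (is.null(scope)) {
    stop("scope (\"anterior\" or \"posterior\") is required for two-column catalogs",
         call. = FALSE)
  }
  scope <- match.arg(scope, c("anterior", "posterior", "both"))
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) {
    return(hpo_catalog(tibble::tibble(
      code = character(), surface = character(), scope = character(),
      layer = character(), provenance = character()
    )))
  }
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  entries <- vector("list", length(rows))
  for (j in seq_along(rows)) {
    p <- parts[[j]]
    rowno <- rows[[j]]
    if (length(p) < 2) {
      stop("row ", rowno, " of ", basename(path),
           ": expected 'code<TAB>surface'", call. = FALSE)
    }
    code <- tryCatch(canonicalize_hpo(p[[1]]), error = function(e) {
      stop("row ", rowno, " of ", basename(path), ": ", conditionMessage(e),
           call. = FALSE)
    })
    surface <- stringr::str_trim(p[[2]])
    if (!nzchar(surface)) {
      stop("row ", rowno, " of ", basename(path), ": empty surface form",
           call. = FALSE)
    }
    entries[[j]] <- tibble::tibble(code = code, surface = surface)
  }
  entries <- dplyr::bind_rows(entries)
  entries$scope <- scope
  entries$layer <- "local"
  entries$provenance <- provenance
  hpo_catalog(entries)
}

.load_catalog_export <- function(lines, path) {
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(hpo_catalog(tibble::tibble(
      code = character(), surface = character(), scope = character(),
      layer = character(), provenance = character()
    )))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 5L)
  if (length(bad) > 0) {
    stop("row ", bad[[1]] + 1L, " of ", basename(path),
         ": expected 5 tab-separated fields", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  hpo_catalog(tibble::tibble(
    code = m[, 1], surface = m[, 2], scope = m[, 3],
    layer = m[, 4], provenance = m[, 5]
  ))
}

#' Merge two catalogs
#'
#' Entries are concatenated and revalidated. Local-layer entries win
#' surface-form collisions against standard-layer entries at lookup
#' time; a collision between two local entries with different codes is a
#' merge error.
#'
#' @param base,local `hpo_catalog` objects.
#' @return The merged `hpo_catalog`; provenance of every entry preserved.
#' @export
merge_catalogs <- function(base, local) {
  stopifnot(inherits(base, "hpo_catalog"), inherits(local, "hpo_catalog"))
  hpo_catalog(dplyr::bind_rows(tibble::as_tibble(base), tibble::as_tibble(local)))
}

#' Add a synonym to the local layer
#'
#' The augmentation primitive: after an expert identifies the correct
#' code for a surface form, the surface is added as a local-layer
#' synonym so that subsequent exact-tier lookup returns that code.
#' Adding a (surface, code) pair that is already in the local layer is a
#' no-op; pointing an existing local surface at a different code is a
#' conflict error (retract first).
#'
#' @param catalog An `hpo_catalog`.
#' @param surface Non-empty surface form.
#' @param code Target HPO code (any accepted spelling).
#' @param scope Scope of the new entry (default `"both"`).
#' @return The updated `hpo_catalog`.
#' @export
add_synonym <- function(catalog, surface, code, scope = "both") {
  stopifnot(inherits(catalog, "hpo_catalog"))
  surface <- stringr::str_squish(stringi::stri_trans_nfc(surface))
  if (!nzchar(surface)) stop("empty surface form", call. = FALSE)
  code <- canonicalize_hpo(code)
  scope <- match.arg(scope, CATALOG_SCOPES)
  norm <- normalize_surface(surface)
  local <- catalog[catalog$layer == "local", ]
  hit <- which(local$norm == norm)
  if (length(hit) > 0) {
    existing <- unique(local$code[hit])
    if (!identical(existing, code)) {
      stop("surface '", surface, "' already maps to ", hpo_curie(existing),
           " in the local layer (requested ", hpo_curie(code), ")", call. = FALSE)
    }
    return(catalog)
  }
  new_row <- tibble::tibble(code = code, surface = surface, scope = scope,
                            layer = "local", provenance = "local-augmentation")
  hpo_catalog(dplyr::bind_rows(tibble::as_tibble(catalog)[CATALOG_COLUMNS], new_row))
}

#' Export a catalog as tab-separated text
#'
#' UTF-8, LF line endings, header
#' `hpo_id  surface  scope  layer  provenance`, rows stable-sorted by
#' (code, surface) so exports are diffable. [load_local_catalog()] reads
#' the format back to an equal catalog.
#'
#' @param catalog An `hpo_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "hpo_catalog"))
  df <- tibble::as_tibble(catalog)
  if (nrow(df) > 0) df <- df[.catalog_order(df), ]
  rows <- if (nrow(df) == 0) character(0) else
    paste(df$code, df$surface, df$scope, df$layer, df$provenance, sep = "\t")
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write catalog to ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(c(CATALOG_TSV_HEADER, rows), con, sep = "\n", useBytes = FALSE)
  invisible(path)
}

#' Compare two catalogs entry-by-entry
#'
#' Equality ignores row order (entries are compared in the stable sort
#' order) but includes scope, layer and provenance.
#'
#' @param a,b `hpo_catalog` objects.
#' @return `TRUE` or `FALSE`.
#' @export
catalogs_equal <- function(a, b) {
  ta <- tibble::as_tibble(a)[CATALOG_COLUMNS]
  tb <- tibble::as_tibble(b)[CATALOG_COLUMNS]
  if (nrow(ta) != nrow(tb)) return(FALSE)
  if (nrow(ta) == 0) return(TRUE)
  ta <- ta[order(ta$code, ta$surface, ta$layer, method = "radix"), ]
  tb <- tb[order(tb$code, tb$surface, tb$layer, method = "radix"), ]
  isTRUE(all.equal(as.data.frame(ta), as.data.frame(tb), check.attributes = FALSE))
}

# Checksum of a catalog's exported text form; used to tie a persisted
# embedding index to the catalog it was built from.
catalog_checksum <- function(catalog) {
  df <- tibble::as_tibble(catalog)
  if (nrow(df) > 0) df <- df[.catalog_order(df), ]
  txt <- paste(df$code, df$surface, df$scope, df$layer, df$provenance,
               sep = "\t", collapse = "\n")
  ints <- utf8ToInt(enc2utf8(txt))
  h1 <- .roll_hash(ints, seed = 17)
  h2 <- .roll_hash(ints, seed = 101, mod = 999983)
  sprintf("%06x%06x", h1, h2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
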