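# HPO identifier handling and surface-form normalization.

#' The ignore sentinel code
#'
#' Local catalogs mark surface forms whose segments must produce no
#' annotation with the code `"0"`. The sentinel is a first-class catalog
#' code but is never emitted as an annotation.
#'
#' @export
HPO_IGNORE <- "0"

#' Canonicalize HPO identifiers
#'
#' Accepts identifiers in any of the common spellings — `"HP:0000541"`,
#' `"0000541"`, `"541"`, or the integer `541` — and returns the canonical
#' 7-digit zero-padded form (`"0000541"`). The ignore sentinel `"0"` is
#' preserved as-is. Canonicalization is idempotent.
#'
#' @param x Character or numeric vector of identifiers.
#' @return Character vector of canonical codes.
#' @examples
#' canonicalize_hpo(c("HP:0000541", "541", "0"))
#' @export
canonicalize_hpo <- function(x) {
  if (length(x) == 0) return(character(0))
  x <- as.character(x)
  vapply(x, function(v) {
    raw <- v
    v <- stringr::str_trim(v)
    v <- sub("^[Hh][Pp]\\s*[:_]\\s*", "", v)
    if (!grepl("^[0-9]+$", v)) {
      stop("invalid HPO code: '", raw, "' (digits or the sentinel \"0\" expected)",
           call. = FALSE)
    }
    n <- suppressWarnings(as.numeric(v))
    if (n == 0) return(HPO_IGNORE)
    if (nchar(sub("^0+", "", v)) > 7) {
      stop("invalid HPO code: '", raw, "' (more than 7 significant digits)",
           call. = FALSE)
    }
    sprintf("%07d", as.integer(n))
  }, character(1), USE.NAMES = FALSE)
}

#' Format a canonical code as an HP CURIE
#'
#' @param code Character vector of canonical codes (see [canonicalize_hpo()]).
#' @return `"HP:NNNNNNN"` strings; the ignore sentinel is returned unchanged.
#' @export
hpo_curie <- function(code) {
  code <- canonicalize_hpo(code)
  ifelse(code == HPO_IGNORE, HPO_IGNORE, paste0("HP:", code))
}

#' @rdname HPO_IGNORE
#' @param code character vector of codes.
#' @export
is_ignore_sentinel <- function(code) {
  canonicalize_hpo(code) == HPO_IGNORE
}

#' Normalize a surface form for exact lookup
#'
#' Unicode NFC, lower case, trimmed, internal whitespace collapsed, and
#' terminal sentence punctuation (`. , ; : ! ?`) stripped. Both catalog
#' surfaces and query segments pass through this normalization, which
#' makes the exact-match tier deterministic.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_surface <- function(x) {
  x <- stringi::stri_trans_nfc(as.character(x))
  x <- stringr::str_to_lower(x)
  x <- stringr::str_squish(x)
  sub("[.,;:!?]+$", "", x)
}

# Stable 32-bit-safe rolling hash used for catalog checksums and the
# hashing embedder. Operates on integer byte/codepoint vectors; all
# intermediates stay below 2^53 so arithmetic is exact in doubles.
.roll_hash <- function(ints, seed = 17, mod = 1000003) {
  h <- seed %% mod
  for (b in ints) h <- (h * 131 + b) %% mod
  h
}
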