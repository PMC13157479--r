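# Pluggable text-generation backend for the pre-processing stages
# (translation, segmentation, finding classification). The packaged
# implementation is a fully deterministic rule-based backend: a
# German->English phrase lexicon, a sentence/separator splitter, and
# trigger-list negation / normal-finding detection. Users may supply
# their own backend object (e.g. wrapping a local language model) by
# implementing the three generics for their class.

#' Read a phrase list
#'
#' One phrase per line; lines starting with `#` and blank lines are
#' skipped; phrases are trimmed.
#'
#' @param path Path to the file.
#' @return Character vector of phrases.
#' @export
read_phrase_list <- function(path) {
  if (!file.exists(path)) stop("phrase list not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- stringr::str_trim(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read a translation lexicon
#'
#' Tab-separated `source <TAB> target` phrase pairs; `#` comment lines
#' and blank lines are skipped.
#'
#' @param path Path to the TSV file.
#' @return Named character vector: `names` are source phrases, values
#'   target phrases.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(stringr::str_trim(lines)) & !grepl("^\\s*#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad) > 0) {
    stop("lexicon row ", bad[[1]], " is not 'source<TAB>target'", call. = FALSE)
  }
  out <- vapply(parts, function(p) stringr::str_trim(p[[2]]), character(1))
  names(out) <- vapply(parts, function(p) stringr::str_trim(p[[1]]), character(1))
  out[!duplicated(names(out))]
}

.pkg_file <- function(...) {
  p <- system.file(..., package = "ophpo", mustWork = FALSE)
  if (!nzchar(p)) stop("packaged file not found: ", file.path(...), call. = FALSE)
  p
}

#' Rule-based generation backend
#'
#' The deterministic fallback behind the translation, segmentation and
#' classification stages. Translation substitutes lexicon phrases
#' (longest first, word-boundary, case-insensitive); tokens absent from
#' the lexicon pass through unchanged. Segmentation splits on sentence
#' boundaries, semicolons, line breaks, and commas outside parentheses.
#' Classification applies, in order: negation triggers (whole-segment
#' scope), normal-finding markers, else pathological.
#'
#' @param lexicon Named character vector (see [read_lexicon()]) or `NULL`
#'   for the packaged German->English ophthalmic lexicon.
#' @param negation_triggers,normal_markers Character vectors of phrases,
#'   or `NULL` for the packaged lists.
#' @return An object of class `rule_backend`.
#' @export
rule_generation_backend <- function(lexicon = NULL, negation_triggers = NULL,
                                    normal_markers = NULL) {
  if (is.null(lexicon)) lexicon <- read_lexicon(.pkg_file("extdata", "de_en_lexicon.tsv"))
  if (is.null(negation_triggers)) {
    negation_triggers <- read_phrase_list(.pkg_file("extdata", "negation_triggers.txt"))
  }
  if (is.null(normal_markers)) {
    normal_markers <- read_phrase_list(.pkg_file("extdata", "normal_markers.txt"))
  }
  lexicon <- lexicon[order(-nchar(names(lexicon)), names(lexicon))]
  compile_any <- function(phrases) {
    if (length(phrases) == 0) return(NULL)
    pats <- vapply(phrases, .phrase_regex, character(1))
    stringr::regex(paste0("(", paste(pats, collapse = ")|("), ")"),
                   ignore_case = TRUE)
  }
  structure(
    list(
      id = "rule-fallback-v1",
      lexicon = lexicon,
      lexicon_patterns = lapply(names(lexicon), function(p)
        stringr::regex(.phrase_regex(p), ignore_case = TRUE)),
      negation_triggers = negation_triggers,
      normal_markers = normal_markers,
      negation_regex = compile_any(negation_triggers),
      normal_regex = compile_any(normal_markers)
    ),
    class = c("rule_backend", "ophpo_generation_backend")
  )
}

#' Stage generics of a generation backend
#'
#' `backend_translate()` maps source-language text to English;
#' `backend_segment()` splits a free-text field into ordered finding
#' strings; `backend_classify()` labels each finding as
#' `"pathological"`, `"normal"` or `"negated"`. `prompt` carries the
#' stage's prompt template (configuration for model-based backends; the
#' rule backend ignores it).
#'
#' @param backend A generation backend object.
#' @param text Character vector of input text.
#' @param prompt Optional prompt template string.
#' @param ... Passed to methods.
#' @return `backend_translate`: character vector; `backend_segment`:
#'   list of character vectors; `backend_classify`: character vector of
#'   status labels.
#' @export
backend_translate <- function(backend, text, prompt = NULL, ...) {
  UseMethod("backend_translate")
}

#' @rdname backend_translate
#' @export
backend_segment <- function(backend, text, prompt = NULL, ...) {
  UseMethod("backend_segment")
}

#' @rdname backend_translate
#' @export
backend_classify <- function(backend, text, prompt = NULL, ...) {
  UseMethod("backend_classify")
}

# word-boundary phrase regex; internal whitespace matches flexibly
.phrase_regex <- function(phrase) {
  esc <- stringr::str_split(stringr::str_squish(phrase), stringr::fixed(" "))[[1]]
  esc <- vapply(esc, function(w) gsub("([][{}()*+?.\\\\^$|])", "\\\\\\1", w),
                character(1))
  paste0("(?<![[:alnum:]])", paste(esc, collapse = "\\s+"), "(?![[:alnum:]])")
}

#' @rdname backend_translate
#' @export
backend_translate.rule_backend <- function(backend, text, prompt = NULL, ...) {
  out <- text
  for (k in seq_along(backend$lexicon)) {
    out <- stringr::str_replace_all(out, backend$lexicon_patterns[[k]],
                                    unname(backend$lexicon[[k]]))
  }
  out
}

# paren-aware splitter: segments end at ; , (outside parens), line
# breaks, or sentence punctuation followed by whitespace/EOL
.split_findings <- function(text) {
  if (is.na(text) || !nzchar(stringr::str_trim(text))) return(character(0))
  chars <- strsplit(text, "", fixed = FALSE)[[1]]
  n <- length(chars)
  depth <- 0L
  cuts <- integer(0)
  for (i in seq_len(n)) {
    ch <- chars[[i]]
    if (ch %in% c("(", "[")) depth <- depth + 1L
    else if (ch %in% c(")", "]")) depth <- max(0L, depth - 1L)
    else if (ch == "\n" || ch == ";") cuts <- c(cuts, i)
    else if (ch == "," && depth == 0L) cuts <- c(cuts, i)
    else if (ch %in% c(".", "!", "?") && depth == 0L &&
             (i == n || grepl("^\\s$", chars[[i + 1L]]))) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, n)
  segs <- vapply(seq_along(starts), function(j) {
    if (starts[[j]] > ends[[j]]) return("")
    paste(chars[starts[[j]]:ends[[j]]], collapse = "")
  }, character(1))
  segs <- stringr::str_squish(segs)
  segs[nzchar(segs)]
}

#' @rdname backend_translate
#' @export
backend_segment.rule_backend <- function(backend, text, prompt = NULL, ...) {
  lapply(text, .split_findings)
}

#' @rdname backend_translate
#' @export
backend_classify.rule_backend <- function(backend, text, prompt = NULL, ...) {
  status <- rep("pathological", length(text))
  if (!is.null(backend$normal_regex)) {
    status[stringr::str_detect(text, backend$normal_regex)] <- "normal"
  }
  if (!is.null(backend$negation_regex)) {
    status[stringr::str_detect(text, backend$negation_regex)] <- "negated"
  }
  status
}

#' Read a prompt template
#'
#' Prompt templates are plain UTF-8 text with an `{input}` placeholder;
#' they are configuration for model-based backends and can be edited in
#' natural language by domain experts. Packaged placeholders live in
#' `extdata/prompts/`.
#'
#' @param stage `"translate"`, `"segment"` or `"classify"`, or a path to
#'   a custom template file.
#' @return The template as one string.
#' @export
read_prompt_template <- function(stage) {
  path <- if (file.exists(stage)) stage else
    .pkg_file("extdata", "prompts", paste0(stage, ".txt"))
  paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
}
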