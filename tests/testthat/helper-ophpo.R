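# Shared fixtures built in code.

# tiny local catalog from in-memory (code, surface) pairs
toy_local_catalog <- function(pairs, scope = "anterior") {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(paste(names(pairs), unname(pairs), sep = "\t"), path)
  load_local_catalog(path, scope = scope)
}

# write a minimal OBO file for a named list id -> list(label, synonyms)
write_toy_obo <- function(terms, path) {
  lines <- c("format-version: 1.2", "")
  for (id in names(terms)) {
    t <- terms[[id]]
    lines <- c(lines, "[Term]", paste0("id: HP:", id), paste0("name: ", t$label))
    for (s in t$synonyms %||% character(0)) {
      lines <- c(lines, sprintf('synonym: "%s" EXACT []', s))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic pseudo-word generator for synthetic surfaces
random_words <- function(n, seed_offset = 0) {
  syll <- c("ret", "cor", "len", "mac", "vit", "pig", "dru", "fov",
            "scler", "irid", "opt", "pap", "chor", "cyst", "fib")
  vapply(seq_len(n), function(i) {
    k <- 2 + (i + seed_offset) %% 3
    paste(syll[(i * seq_len(k) * 7 + seed_offset) %% length(syll) + 1],
          collapse = "")
  }, character(1))
}

# single-record tibble shortcut
one_record <- function(anterior = "", posterior = "", language = "en",
                       id = "r1") {
  clinical_records(id, anterior, posterior, language)
}
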