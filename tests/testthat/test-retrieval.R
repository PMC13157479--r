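test_that("index has one entry per surface, deterministically embedded", {
  cat <- toy_local_catalog(c("1" = "alpha sign", "2" = "beta sign",
                             "3" = "gamma sign", "4" = "delta sign",
                             "5" = "epsilon sign"))
  idx <- build_index(cat)
  expect_equal(nrow(idx$entries), 5)
  expect_equal(nrow(idx$vectors), 5)
  idx2 <- build_index(cat)
  expect_identical(idx$vectors, idx2$vectors)
  # entry order matches the exported stable sort (code, surface)
  p <- withr::local_tempfile(fileext = ".tsv")
  export_catalog(cat, p)
  exported <- read.delim(p)
  expect_equal(idx$entries$surface, exported$surface)
  expect_error(build_index(hpo_catalog(data.frame(
    code = character(), surface = character(), scope = character(),
    layer = character(), provenance = character()))), "empty catalog")
})

test_that("exact tier resolves catalog surfaces with similarity 1", {
  idx <- build_index(build_fixture_catalog())
  m <- map_segment("retinal detachment", idx)
  expect_equal(m$code, "0000541")
  expect_equal(m$tier, "exact")
  expect_equal(m$similarity, 1.0)
  m2 <- map_segment("Eyelash loss", idx)
  expect_equal(m2$code, "0011457")
  expect_equal(m2$tier, "exact")
})

test_that("embedding tier equals the exhaustive cosine oracle", {
  set.seed(31)
  n <- 60
  surfaces <- paste(random_words(n), random_words(n, 7), seq_len(n))
  cat <- toy_local_catalog(stats::setNames(surfaces, as.character(seq_len(n))))
  backend <- hash_embedding_backend()
  idx <- build_index(cat, backend)
  queries <- c(
    paste(random_words(25, 3), "x"),
    paste0(substr(surfaces[1:25], 1, 8), "zz") # perturbed catalog surfaces
  )
  ent <- idx$entries
  for (q in queries) {
    got <- map_segment(q, idx)
    if (got$tier == "exact") next
    # independent oracle: per-entry cosine from first principles
    qv <- as.numeric(embed_texts(backend, normalize_surface(q)))
    sims <- vapply(seq_len(nrow(ent)), function(i) {
      v <- as.numeric(embed_texts(backend, ent$norm[[i]]))
      sum(qv * v) / sqrt(sum(qv^2) * sum(v^2))
    }, numeric(1))
    best <- max(sims)
    cand <- which(sims >= best - 1e-12)
    rank <- order(ifelse(ent$layer[cand] == "local", 0L, 1L), ent$code[cand])
    expect_equal(got$code, ent$code[[cand[rank[1]]]])
    expect_equal(got$similarity, best, tolerance = 1e-9)
  }
})

test_that("exact cosine ties break local-first then smallest code", {
  # a stub backend embedding every text identically forces an all-way tie
  const_backend <- structure(list(id = "const", dim = 4L),
                             class = c("const_backend",
                                       "ophpo_embedding_backend"))
  assign("embed_texts.const_backend",
         function(backend, texts, ...) {
           matrix(rep(c(1, 0, 0, 0), length(texts)),
                  ncol = 4, byrow = TRUE)
         }, envir = globalenv())
  withr::defer(rm("embed_texts.const_backend", envir = globalenv()))
  obo <- withr::local_tempfile(fileext = ".obo")
  write_toy_obo(list(`0000100` = list(label = "aaa standard")), obo)
  std <- load_hpo_subset(obo)
  loc <- toy_local_catalog(c("500" = "zzz local", "700" = "mmm local"))
  idx <- build_index(merge_catalogs(std, loc), const_backend)
  m <- map_segment("unrelated query", idx)
  expect_equal(m$tier, "embedding")
  # local layer wins over the standard entry despite its larger code;
  # among local entries the smallest code wins
  expect_equal(m$code, "0000500")
})

test_that("exact tier precedes embeddings even when vectors disagree", {
  const_backend <- structure(list(id = "const", dim = 4L),
                             class = c("const_backend",
                                       "ophpo_embedding_backend"))
  assign("embed_texts.const_backend",
         function(backend, texts, ...) {
           matrix(rep(c(1, 0, 0, 0), length(texts)), ncol = 4, byrow = TRUE)
         }, envir = globalenv())
  withr::defer(rm("embed_texts.const_backend", envir = globalenv()))
  cat <- toy_local_catalog(c("1" = "Roth spot", "2" = "Drusen"))
  idx <- build_index(cat, const_backend)
  m <- map_segment("roth spot.", idx) # normalizes to the catalog surface
  expect_equal(m$tier, "exact")
  expect_equal(m$code, "0000001")
})

test_that("augmentation fixpoint: added synonym resolves via exact tier", {
  cat <- build_fixture_catalog()
  cat2 <- add_synonym(cat, "Salzmann's nodular degeneration", "0000481")
  idx <- build_index(cat2)
  m <- map_segment("Salzmann's nodular degeneration", idx)
  expect_equal(m$tier, "exact")
  expect_equal(m$code, "0000481")
})

test_that("ignore-sentinel matches yield no annotation", {
  idx <- build_index(build_fixture_catalog())
  m <- map_segment("Motility", idx)
  expect_true(is_ignore_sentinel(m$code))
  res <- annotate_record(one_record("Motility"), idx)
  expect_equal(res$codes, character(0))
  expect_equal(nrow(res$annotations), 0)
})

test_that("record-level predictions are sets; detail list keeps provenance", {
  idx <- build_index(build_fixture_catalog())
  res <- annotate_record(one_record("Roth spot; Roth spot", "", "en"),
                         idx)
  expect_equal(res$codes, "0031805")
  expect_equal(nrow(res$annotations), 2)
  planted <- c("Eyelash loss", "Red cataract", "Roth spot")
  res2 <- annotate_record(one_record(paste(planted[1:2], collapse = "; "),
                                     planted[3], "en"), idx)
  expect_equal(res2$codes, sort(c("0011457", "0100018", "0031805")))
})

test_that("exact-only mode and min_similarity return no match when unmet", {
  idx <- build_index(build_fixture_catalog())
  expect_null(map_segment("completely novel finding", idx,
                          use_embedding = FALSE))
  expect_null(map_segment("completely novel finding", idx,
                          min_similarity = 0.999))
  m <- map_segment("completely novel finding", idx, min_similarity = -1)
  expect_false(is.null(m))
})

test_that("index save/load round-trips and checks backend identity", {
  cat <- build_fixture_catalog()
  idx <- build_index(cat)
  d <- withr::local_tempdir()
  save_index(idx, d)
  idx2 <- load_index(d)
  expect_identical(idx$entries$norm, idx2$entries$norm)
  expect_equal(idx$vectors, idx2$vectors)
  expect_identical(idx$checksum, idx2$checksum)
  expect_identical(idx2$checksum, catalog_checksum(cat))
  m <- map_segment("Eyelash loss", idx2)
  expect_equal(m$code, "0011457")
  other <- hash_embedding_backend(dim = 64)
  expect_error(load_index(d, backend = other), "backend mismatch")
})
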