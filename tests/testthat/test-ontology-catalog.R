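test_that("ontology subset loads with labels and synonyms resolvable", {
  cat <- load_hpo_subset(system.file("extdata", "hpo_retinal_detachment.obo",
                                     package = "ophpo"))
  expect_s3_class(cat, "hpo_catalog")
  expect_equal(lookup_code(cat, "retinal detachment"), "0000541")
  expect_equal(lookup_code(cat, "Amotio retinae"), "0000541")
  expect_true(all(cat$layer == "standard"))
  expect_true(all(cat$scope == "both"))
})

test_that("empty ontology file yields an empty catalog", {
  p <- withr::local_tempfile(fileext = ".obo")
  writeLines("format-version: 1.2", p)
  cat <- load_hpo_subset(p)
  expect_equal(nrow(cat), 0)
})

test_that("surface count equals labels plus synonyms, tallied independently", {
  # brute-force oracle: count labels + synonyms while writing the file
  terms <- list(
    `0000001` = list(label = "Alpha finding", synonyms = c("alfa", "first sign")),
    `0000002` = list(label = "Beta finding", synonyms = character(0)),
    `0000003` = list(label = "Gamma finding", synonyms = "third sign")
  )
  expected_n <- sum(vapply(terms, function(t) 1L + length(t$synonyms), integer(1)))
  p <- withr::local_tempfile(fileext = ".obo")
  write_toy_obo(terms, p)
  cat <- load_hpo_subset(p)
  expect_equal(nrow(cat), expected_n)
  expect_equal(nrow(surface_index(cat)), expected_n)
})

test_that("OBO and obographs JSON dialects load the same catalog", {
  obo <- withr::local_tempfile(fileext = ".obo")
  write_toy_obo(list(`0000541` = list(label = "Retinal detachment",
                                      synonyms = "Amotio retinae")), obo)
  js <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(graphs = list(list(nodes = list(list(
    id = "http://purl.obolibrary.org/obo/HP_0000541",
    lbl = "Retinal detachment",
    meta = list(synonyms = list(list(pred = "hasExactSynonym",
                                     val = "Amotio retinae")))
  ))))), auto_unbox = TRUE), js)
  expect_true(catalogs_equal(load_hpo_subset(obo), load_hpo_subset(js)))
})

test_that("malformed ontology input names the offending line or id", {
  p <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", "[Term]", "id: HP:0000001"), p)
  expect_error(load_hpo_subset(p), "no name")
  writeLines(c("[Term]", "id: HP:0000001", "name: A", "",
               "[Term]", "id: HP:0000001", "name: B"), p)
  expect_error(load_hpo_subset(p), "duplicate concept id")
  writeLines(c("[Term]", "id: HP:0000001", "name: A", "not a key value"), p)
  expect_error(load_hpo_subset(p), "line 4")
})

test_that("local catalog rows canonicalize and keep the ignore sentinel", {
  cat <- toy_local_catalog(c("11457" = "Eyelash loss", "0" = "Motility"),
                           scope = "anterior")
  expect_equal(lookup_code(cat, "Eyelash loss"), "0011457")
  expect_equal(lookup_code(cat, "Motility"), "0")
  expect_true(all(cat$layer == "local"))
  expect_equal(sum(cat$code == "0"), 1)
})

test_that("local catalog row errors carry the row number", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("11457\tEyelash loss", "abc\tBroken row"), p)
  expect_error(load_local_catalog(p, scope = "anterior"), "row 2")
  writeLines(c("11457\t   "), p)
  expect_error(load_local_catalog(p, scope = "anterior"), "empty surface")
  writeLines("11457\tEyelash loss", p)
  expect_error(load_local_catalog(p), "scope")
})

test_that("export then reload reproduces an identical catalog", {
  cat <- build_fixture_catalog()
  p <- withr::local_tempfile(fileext = ".tsv")
  export_catalog(cat, p)
  again <- load_local_catalog(p)
  expect_true(catalogs_equal(cat, again))
  # line count = entries + header
  expect_equal(length(readLines(p)), nrow(cat) + 1L)
  # exporting the reloaded catalog is byte-identical (stable sort)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  export_catalog(again, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("export of an empty catalog is a header-only file", {
  p <- withr::local_tempfile(fileext = ".tsv")
  export_catalog(hpo_catalog(data.frame(code = character(),
                                        surface = character(),
                                        scope = character(),
                                        layer = character(),
                                        provenance = character())), p)
  expect_equal(readLines(p), "hpo_id\tsurface\tscope\tlayer\tprovenance")
  expect_equal(nrow(load_local_catalog(p)), 0)
})

test_that("merge is identity with an empty catalog and unions surfaces", {
  empty <- hpo_catalog(data.frame(code = character(), surface = character(),
                                  scope = character(), layer = character(),
                                  provenance = character()))
  a <- toy_local_catalog(c("1" = "alpha sign", "2" = "beta sign"))
  b <- toy_local_catalog(c("3" = "gamma sign"), scope = "posterior")
  expect_true(catalogs_equal(merge_catalogs(a, empty), a))
  merged <- merge_catalogs(a, b)
  # set-union oracle over normalized surfaces
  oracle <- union(a$norm, b$norm)
  expect_setequal(surface_index(merged)$norm, oracle)
  expect_equal(nrow(surface_index(merged)), length(oracle))
})

test_that("local layer wins collisions against standard; local-local collides", {
  obo <- withr::local_tempfile(fileext = ".obo")
  write_toy_obo(list(`0000541` = list(label = "Retinal detachment")), obo)
  std <- load_hpo_subset(obo)
  loc <- toy_local_catalog(c("99" = "Retinal detachment"))
  merged <- merge_catalogs(std, loc)
  expect_equal(lookup_code(merged, "retinal detachment"), "0000099")
  # both entries retained with their provenance
  expect_equal(nrow(merged), 2)
  loc2 <- toy_local_catalog(c("88" = "Retinal detachment"))
  expect_error(merge_catalogs(loc, loc2), "collision in local layer")
})

test_that("the standard layer refuses the ignore sentinel", {
  expect_error(hpo_catalog(data.frame(
    code = "0", surface = "Motility", scope = "both",
    layer = "standard", provenance = "ontology")), "sentinel")
})

test_that("add_synonym makes the surface resolvable and is idempotent", {
  cat <- build_fixture_catalog()
  cat2 <- add_synonym(cat, "Amotio retinae", "0000541")
  expect_equal(lookup_code(cat2, "Amotio retinae"), "0000541")
  # adding an existing (surface, code) pair in the local layer is a no-op
  cat3 <- add_synonym(cat2, "Amotio retinae", "541")
  expect_true(catalogs_equal(cat2, cat3))
  expect_error(add_synonym(cat2, "Amotio retinae", "999"),
               "already maps")
})

test_that("k distinct additions grow the local layer by exactly k", {
  cat <- build_fixture_catalog()
  surfaces <- paste("new synonym", 1:7)
  before <- sum(cat$layer == "local")
  for (i in seq_along(surfaces)) {
    cat <- add_synonym(cat, surfaces[[i]], "0000541")
  }
  expect_equal(sum(cat$layer == "local"), before + length(surfaces))
  expect_true(all(cat$provenance[cat$surface %in% surfaces] ==
                    "local-augmentation"))
})
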