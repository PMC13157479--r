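# Synthetic bilingual ophthalmology corpora with known ground truth.
# Each record mixes pathological findings drawn from a synonym catalog
# (about 2.5 per record on average, matching the study's reported mean)
# with normal and negated distractor findings, in German or English
# surface forms, split across anterior- and posterior-segment fields.

#' Generator configuration
#'
#' @param n_records Number of records.
#' @param seed Integer RNG seed; identical config + seed reproduce the
#'   corpus exactly.
#' @param mean_findings Poisson mean of pathological findings per record
#'   (default 2.5, the study-scale average).
#' @param p_negated,p_normal Target fractions of negated / normal
#'   distractor segments among all segments (defaults 0.2 / 0.3); their
#'   sum must stay below 1.
#' @param p_german_surface Probability that a planted finding uses its
#'   German surface variant where the packaged lexicon has one
#'   (default 0.5).
#' @param synonym_miss_rate Probability that a planted surface is
#'   replaced by an out-of-catalog paraphrase while its code stays in
#'   the truth set, simulating synonym misses (default 0).
#' @param catalog Catalog to draw findings from (default
#'   [build_fixture_catalog()]).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_records, seed, mean_findings = 2.5,
                             p_negated = 0.2, p_normal = 0.3,
                             p_german_surface = 0.5, synonym_miss_rate = 0,
                             catalog = build_fixture_catalog()) {
  stopifnot(n_records >= 1, mean_findings >= 0)
  for (p in c(p_negated, p_normal, p_german_surface, synonym_miss_rate)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p_negated + p_normal >= 1) {
    stop("p_negated + p_normal must be below 1", call. = FALSE)
  }
  stopifnot(inherits(catalog, "hpo_catalog"))
  structure(
    list(n_records = as.integer(n_records), seed = as.integer(seed),
         mean_findings = mean_findings, p_negated = p_negated,
         p_normal = p_normal, p_german_surface = p_german_surface,
         synonym_miss_rate = synonym_miss_rate, catalog = catalog),
    class = "generator_config"
  )
}

#' The packaged fixture catalog
#'
#' The local anterior- and posterior-segment example catalogs (including
#' their ignore-sentinel rows) merged with the standard-layer ontology
#' subset containing the retinal-detachment concept (HP:0000541, with
#' its Latin synonym).
#'
#' @return An `hpo_catalog`.
#' @export
build_fixture_catalog <- function() {
  anterior <- load_local_catalog(.pkg_file("extdata", "anterior_catalog.tsv"),
                                 scope = "anterior")
  posterior <- load_local_catalog(.pkg_file("extdata", "posterior_catalog.tsv"),
                                  scope = "posterior")
  standard <- load_hpo_subset(.pkg_file("extdata", "hpo_retinal_detachment.obo"))
  merge_catalogs(merge_catalogs(anterior, posterior), standard)
}

# English/German normal-finding distractors with their anatomical scope.
.NORMAL_DISTRACTORS <- data.frame(
  en = c("Cornea clear", "Lens unremarkable", "Anterior chamber quiet",
         "Vitreous clear", "Optic disc normal", "Retina attached"),
  de = c("Hornhaut klar", "Linse unauffällig", "Vorderkammer reizfrei",
         "Glaskörper klar", "Papille regelrecht", "Netzhaut anliegend"),
  scope = c("anterior", "anterior", "anterior",
            "posterior", "posterior", "posterior"),
  stringsAsFactors = FALSE
)

# Surfaces usable as atomic planted findings: non-sentinel, and free of
# the separators the fallback splitter cuts on (so one finding is
# guaranteed to survive segmentation as one segment).
.plantable_surfaces <- function(catalog) {
  df <- tibble::as_tibble(catalog)
  df <- df[df$code != HPO_IGNORE & !grepl("[,;.\n]", df$surface), ]
  df[, c("code", "surface", "norm", "scope")]
}

# inverse lexicon: normalized English surface -> German variant
.german_variants <- function() {
  lex <- read_lexicon(.pkg_file("extdata", "de_en_lexicon.tsv"))
  inv <- names(lex)
  names(inv) <- normalize_surface(unname(lex))
  inv[!duplicated(names(inv))]
}

#' Generate a synthetic corpus with ground truth
#'
#' Per record, `k ~ Poisson(mean_findings)` pathological findings are
#' planted as DISTINCT codes (one surface each), mixed with Poisson
#' numbers of normal and negated distractor segments whose rates are
#' chosen so the expected segment fractions match `p_normal` and
#' `p_negated`. Findings and distractors may appear as German surface
#' variants; fields are assembled per eye segment, segments joined by
#' "; ". With `synonym_miss_rate` r, each planted surface is replaced
#' with probability r by the out-of-catalog paraphrase
#' `"evidence of <surface>"` while its code stays in the truth set.
#'
#' @param config A [generator_config()].
#' @return List: `records` (tibble consumed by [annotate_corpus()]),
#'   `truth` (named list record_id -> sorted code set), `findings`
#'   (manifest tibble: `record_id`, `scope`, `code`, `surface`,
#'   `text_planted`, `expected_segment` — the English segment text the
#'   pipeline should see after translation —, `corrupted`, `german`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  plantable <- .plantable_surfaces(config$catalog)
  if (nrow(plantable) == 0) {
    stop("catalog has no plantable pathological surfaces", call. = FALSE)
  }
  for (sc in c("anterior", "posterior")) {
    if (!any(plantable$scope %in% c(sc, "both"))) {
      stop("catalog lacks plantable ", sc, "-scope entries", call. = FALSE)
    }
  }
  variants <- .german_variants()
  codes_pool <- unique(plantable$code)
  denom <- 1 - config$p_normal - config$p_negated
  rate_scale <- max(config$mean_findings, 1)
  lambda_normal <- rate_scale * config$p_normal / denom
  lambda_negated <- rate_scale * config$p_negated / denom

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  records <- vector("list", config$n_records)
  truth <- vector("list", config$n_records)
  manifests <- vector("list", config$n_records)
  for (i in seq_len(config$n_records)) {
    rid <- sprintf("rec%05d", i)
    k <- min(stats::rpois(1, config$mean_findings), length(codes_pool))
    planted <- .plant_findings(k, plantable, codes_pool, variants, config)
    segs <- list(anterior = character(0), posterior = character(0))
    if (k > 0) {
      planted$record_id <- rid
      for (j in seq_len(nrow(planted))) {
        segs[[planted$scope[[j]]]] <- c(segs[[planted$scope[[j]]]],
                                        planted$text_planted[[j]])
      }
    }
    segs <- .add_distractors(segs, lambda_normal, lambda_negated,
                             plantable, variants, config)
    if (length(segs$anterior) + length(segs$posterior) == 0) {
      # processing requires at least one non-empty field
      d <- .NORMAL_DISTRACTORS[sample.int(nrow(.NORMAL_DISTRACTORS), 1), ]
      segs[[d$scope]] <- d$en
    }
    records[[i]] <- tibble::tibble(
      record_id = rid,
      anterior_text = paste(sample(segs$anterior), collapse = "; "),
      posterior_text = paste(sample(segs$posterior), collapse = "; "),
      language = "de"
    )
    truth[[i]] <- if (k > 0) sort(unique(planted$code)) else character(0)
    names(truth)[i] <- rid
    if (k > 0) manifests[[i]] <- planted
  }
  findings <- dplyr::bind_rows(manifests)
  if (nrow(findings) > 0) {
    findings <- findings[, c("record_id", "scope", "code", "surface",
                             "text_planted", "expected_segment",
                             "corrupted", "german")]
  } else {
    findings <- tibble::tibble(record_id = character(), scope = character(),
                               code = character(), surface = character(),
                               text_planted = character(),
                               expected_segment = character(),
                               corrupted = logical(), german = logical())
  }
  list(records = dplyr::bind_rows(records), truth = truth, findings = findings)
}

.plant_findings <- function(k, plantable, codes_pool, variants, config) {
  if (k == 0) return(NULL)
  codes <- sample(codes_pool, k)
  rows <- lapply(codes, function(cd) {
    cands <- plantable[plantable$code == cd, ]
    cands[sample.int(nrow(cands), 1), ]
  })
  planted <- dplyr::bind_rows(rows)
  planted$scope <- ifelse(planted$scope == "both",
                          ifelse(stats::runif(k) < 0.5, "anterior", "posterior"),
                          planted$scope)
  planted$corrupted <- stats::runif(k) < config$synonym_miss_rate
  use_german <- stats::runif(k) < config$p_german_surface
  planted$german <- !planted$corrupted & use_german &
    planted$norm %in% names(variants)
  planted$expected_segment <- ifelse(
    planted$corrupted, paste("evidence of", tolower(planted$surface)),
    planted$surface)
  planted$text_planted <- planted$expected_segment
  planted$text_planted[planted$german] <-
    unname(variants[planted$norm[planted$german]])
  planted
}

.add_distractors <- function(segs, lambda_normal, lambda_negated,
                             plantable, variants, config) {
  n_norm <- stats::rpois(1, lambda_normal)
  n_neg <- stats::rpois(1, lambda_negated)
  for (d in seq_len(n_norm)) {
    row <- .NORMAL_DISTRACTORS[sample.int(nrow(.NORMAL_DISTRACTORS), 1), ]
    text <- if (stats::runif(1) < config$p_german_surface) row$de else row$en
    segs[[row$scope]] <- c(segs[[row$scope]], text)
  }
  for (d in seq_len(n_neg)) {
    row <- plantable[sample.int(nrow(plantable), 1), ]
    scope <- if (row$scope == "both") {
      if (stats::runif(1) < 0.5) "anterior" else "posterior"
    } else row$scope
    german <- stats::runif(1) < config$p_german_surface &&
      row$norm %in% names(variants)
    text <- if (german) paste("keine", unname(variants[[row$norm]]))
    else paste("no", tolower(row$surface))
    segs[[scope]] <- c(segs[[scope]], text)
  }
  segs
}

#' Write a generated corpus to disk
#'
#' Emits `records.jsonl` (the record format consumed by the pipeline),
#' `truth.jsonl` (ground-truth code sets) and `findings.tsv` (the
#' planting manifest).
#'
#' @param corpus Result of [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec_path <- file.path(dir, "records.jsonl")
  truth_path <- file.path(dir, "truth.jsonl")
  man_path <- file.path(dir, "findings.tsv")
  write_records(corpus$records, rec_path)
  write_code_sets(corpus$truth, truth_path)
  f <- corpus$findings
  writeLines(
    c(paste(names(f), collapse = "\t"),
      if (nrow(f) > 0)
        do.call(paste, c(lapply(f, as.character), sep = "\t"))),
    man_path, useBytes = FALSE
  )
  invisible(c(records = rec_path, truth = truth_path, findings = man_path))
}
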