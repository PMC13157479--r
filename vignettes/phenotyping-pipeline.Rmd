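---
title: "Methods: annotating ophthalmology letters with HPO codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating ophthalmology letters with HPO codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ophpo)
```

## The problem

Physicians' letters in ophthalmology describe anterior- and
posterior-segment findings as free text, in local dialect, often in
German, and mixed with normal findings and explicit rule-outs
("no retinal detachment"). Turning these letters into Human Phenotype
Ontology (HPO) codes yields structured, interoperable deep phenotypes
usable for registries and research, and — because only codes leave the
text — supports on-site, privacy-preserving processing.

`ophpo` implements that conversion as a four-stage pipeline:

1. **Translation** of German notes to English,
2. **Segmentation** of each free-text field into discrete findings,
3. **Exclusion and negation**: normal findings and ruled-out
   pathologies are dropped,
4. **Mapping**: each remaining pathological finding is assigned exactly
   one HPO code by an exact-match tier over a layered synonym catalog,
   falling back to a K = 1 cosine nearest-neighbour search in embedding
   space.

Stages 1–3 are defined against a pluggable *generation backend*. The
package ships a fully deterministic rule-based backend (lexicon
substitution, separator-based splitting, trigger-list classification);
sites with a local language model can substitute their own backend
object without touching the rest of the pipeline. Prompt templates are
plain-text configuration with an `{input}` placeholder, editable by
domain experts.

## The synonym catalog and its layers

The catalog maps *surface forms* (labels, synonyms, local phrasings) to
codes and has two layers:

* the **standard layer**, loaded from an ontology file (OBO 1.2 or
  HPO-style obographs JSON), and
* the **local layer**, curated per site and per eye segment, loaded from
  two-column `code<TAB>surface` files.

Surface forms are normalized (Unicode NFC, lower case, whitespace
collapsed, terminal punctuation stripped) before lookup, which makes the
exact tier deterministic. Within a layer a surface may map to only one
code — collisions are load errors — while across layers the local layer
wins, because it is the curated authority. Codes are stored 7-digit
zero-padded (`HP:0000541` prints as such; local files may write `541`).

The local catalog reserves the code `"0"` as an **ignore sentinel**:
surfaces mapped to it (e.g. administrative remarks such as
"Visualisation improved") are legitimate retrieval targets whose
segments must produce *no* annotation. The sentinel is first-class in
the catalog and the index, and is filtered exactly once, at annotation
time, so no downstream consumer ever sees it.

## Retrieval: exact tier, then K = 1, no threshold

Mapping is deliberately unconditional: every pathological finding is
assigned its single closest catalog entry (K = 1), with the cosine
similarity recorded so callers may post-filter (`min_similarity`,
default off). The trade-off is explicit: concepts absent from the
catalog are assigned their nearest existing neighbour rather than
abstained on; the correction loop below is the designed remedy.

The exact tier sits above the embedding search. For identical strings
any reasonable embedder would return the same winner, but the exact
tier makes the augmentation guarantee — "after a correction, this
surface resolves to this code" — independent of embedding geometry.
Exact cosine ties break to the local layer first, then to the smallest
code; both rules are arbitrary but fixed, so results are reproducible.

The packaged embedding backend is a deterministic signed character
n-gram hashing embedder (default: 3-grams, 256 dimensions, fixed hash
seed, vectors L2-normalized at build time so dot product equals
cosine). It captures lexical similarity, which suffices once
translation has normalized the language; it does not model semantics,
and the backend interface (`embed_texts()`) exists precisely so a
trained sentence embedder can be dropped in. An optional instruction
prefix is supported for instruction-tuned embedders and defaults to
empty. Indexes persist as text (entries TSV, `%.17g` vector matrix,
JSON sidecar with backend identity and a catalog checksum): catalogs
are small, and text keeps indexes diffable and portable.

## The augmentation loop

When retrieval returns a wrong code, the reviewer logs
`(surface, predicted, correct)`. Corrections are applied in batches,
all-or-nothing, so the catalog moves between reviewable states;
conflicting corrections for one surface abort the batch. Applying a
correction adds the surface as a local-layer synonym; the exact tier
then guarantees the fix. Corrections are logged at the surface-form
level, so one correction generalizes to every future occurrence.
Phenotypes that do not exist in the ontology at all are logged with a
MISSING marker and exported as a TSV for upstream submission.

The correction log carries a corpus provenance tag; the CLI refuses to
apply corrections tagged `validation`, keeping the catalog's training
signal separate from any held-out evaluation set.

## Evaluation

Predictions and ground truth are compared per record as *sets* of codes
(duplicates collapse — Jaccard is a set measure). With `tp`, `fp`, `fn`
the usual pooled counts:

* Jaccard = tp / (tp + fp + fn), precision = tp / (tp + fp),
  recall = tp / (tp + fn), F1 = 2·tp / (2·tp + fp + fn),
  so Jaccard = F1 / (2 − F1) wherever both are defined.
* A record with no pathology and no predictions scores 1.0 on all
  metrics (the pipeline was right); if exactly one side is empty, all
  metrics are 0. The first convention keeps perfectly normal records
  from dragging medians down; both are degenerate-case choices the
  metrics themselves do not dictate.
* The report gives **both** medians of per-record metrics (the headline
  presentation) and micro-pooled metrics over summed counts, plus mean
  and total terms per record for predictions and truth. The two
  aggregations answer different questions and need not agree, so both
  are always emitted.

## The synthetic corpus generator

Real letters cannot ship with the package, so every end-to-end property
is exercised on generated corpora with known ground truth. Per record:

* the number of pathological findings is Poisson with mean 2.5 (the
  study-scale average); findings are sampled as **distinct** codes, so
  the truth-set size equals the draw and, under corruption (below),
  misses are independent Bernoulli events — which is what makes the
  binomial degradation check well-posed;
* surfaces are drawn from the catalog, excluding sentinel rows and
  surfaces containing segment separators (`, ; .` or newlines), since
  the splitter would cut those into fragments and the planted ground
  truth would no longer correspond to an atomic segment;
* with probability 0.5 a planted finding appears as its German variant
  from the packaged lexicon (exercising translation); normal and
  negated distractors are interleaved with Poisson counts whose rates
  are set so the *expected fractions* of segments match `p_normal`
  (0.3) and `p_negated` (0.2); with `mean_findings = 0` the rates are
  kept positive so records still contain distractor text;
* with `synonym_miss_rate` r, a planted surface is replaced by the
  out-of-catalog paraphrase `"evidence of <surface>"` while its code
  stays in the truth set. The paraphrase deterministically defeats the
  exact tier, so exact-tier-only micro-recall concentrates at 1 − r.

What passing these tests shows — and does not show: the generator
emulates the *structure* of the data (finding counts, bilingual
surfaces, distractors, synonym gaps), not clinical prose style,
abbreviations, or out-of-lexicon German. Perfect scores on noise-free
synthetic corpora validate the machinery end to end; they say nothing
about performance on real letters, which depends on the quality of the
backends and the curated catalog.

## Problem sizes and numerical choices

The shipped test suite runs the noise-free end-to-end check at 200
records, the degradation/augmentation loop at 800 records (about 2,000
planted findings, enough for the 99% binomial band around recall 0.7 to
be ±0.026), generator calibration at 2,000 records, the retrieval
oracle at 400 catalog surfaces × 120 queries, and the metric identities
at 10,000 random set pairs. These sizes give stable statistics at
desk scale. Floating-point cosine ties are treated as exact ties only
(no epsilon band); the hashing embedder resolves sign-cancelled
zero vectors to a fixed basis vector so normalization is total.

## Known limitations

* Stages 1–3 have no independent validation here; only end-to-end
  behaviour is tested (the rule backend is a deterministic floor, not a
  model of clinical language).
* Negation scope is the whole segment: segmentation is assumed to have
  isolated atomic findings, so no token-window scoping is applied.
  "Normal" and "negated" are recorded as distinct statuses but both are
  excluded from mapping.
* The catalog mapping is flat — no ontology graph semantics, ancestor
  closure, or term similarity beyond surface embeddings.
* K = 1 without threshold means out-of-catalog concepts are silently
  mapped to neighbours; monitor similarity values and run the
  correction loop.
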