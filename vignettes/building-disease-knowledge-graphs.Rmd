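---
title: "Building and validating a disease-centric knowledge graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating a disease-centric knowledge graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgcraft)
```

`kgcraft` turns heterogeneous biomedical resources into one typed,
disease-centric knowledge graph and provides the statistical checks needed
to trust the result. This vignette explains the procedure, the parameters
that matter, the numerical and design choices made where the design was
genuinely open, and what the bundled synthetic data can and cannot show.

## The graph model

The graph has a closed vocabulary: 10 node types (`kg_node_types()`) and 30
relation types (`kg_relation_types()`), each relation declaring its
admissible endpoint pair. Undirected semantics are represented physically
as two directed rows per edge; the serialized CSV therefore contains an
even number of edge rows and `validate_kg()` treats a missing mirror row as
a violation. Node indices are consecutive integers from 0, assigned by
sorting distinct nodes on `(node_type, node_source, node_id)` — a
deterministic rule chosen so that a row permutation of the input yields an
identical graph. No claim is made that these indices coincide with any
externally published file's indices; only the schema is shared.

Equality of graphs is always judged under canonical ordering (nodes by
index, edges lexicographically by relation and endpoints), which makes
round-trip tests and diffs deterministic.

## Ingest filters

Each resource adapter applies its filter and logs what it removed, so that
row conservation (`input = output + dropped`, expansions logged with
multiplicity) is checkable on every run. The thresholds, all exposed
through `ingest_config()`:

* **Expression calls** — keep rows with quality `"gold quality"`, FDR-corrected
  *p* ≤ 0.01 (inclusive), and expression rank strictly below 25,000. The
  strict/inclusive asymmetry is deliberate and tested at both boundaries.
  Whether the rank filter should also apply to *absent* calls is not
  derivable from the sources that describe this filtering; the adapter
  applies all three filters uniformly by default and exposes
  `bgee_rank_applies_to_absent = FALSE` for the alternative reading.
* **Concept selection** — of the 127 semantic types in a concept
  metathesaurus, the 11 belonging to the Disorder semantic group are kept
  (`umls_disorder_types()`); concept atoms and definitions are restricted
  to English.
* **Side effects** — only rows coded at the MedDRA preferred-term level
  survive; drug identifiers then pass through a two-step compound→ATC→drug
  chain, and rows with a broken chain are dropped with a reason.
* **Identifier mapping** — one-to-many mappings expand to one row per
  target by default (`policy = "expand"`); the resulting duplicates are
  collapsed later at assembly. The alternative `policy = "drop"` discards
  ambiguous rows instead. Missing identifiers are dropped at ingest rather
  than at assembly so failures stay attributable to their resource.

## Phenotype/disease overlap resolution

Disease and phenotype vocabularies maintained by one initiative share
numbering, so the same entity can appear in both. The overlap set *P*
contains every phenotype term whose zero-padded numeric suffix equals a
disease term's suffix, or that is cross-referenced from a disease term.
Rewiring then enforces a single role per entity: phenotype–phenotype edges
with one endpoint in *P* become disease–phenotype edges, with both
endpoints disease–disease; protein–phenotype edges become protein–disease;
disease–phenotype and drug–phenotype edges onto *P* are dropped outright,
because converting them would inject noise into the carefully curated
drug–disease label sets. Two choices here were open:

* A *P* member mapping to several disease terms duplicates the rewired
  edge per target and deduplicates at assembly — consistent with the
  expand policy of identifier mapping, and logged.
* Converted phenotype–phenotype edges are labelled
  `disease_phenotype_positive`: it is the only disease–phenotype relation
  family in the vocabulary, and a hierarchy-derived link is a positive
  association.

Rewiring is a fixed point: a second pass changes nothing, because no
phenotype endpoint in *P* survives the first.

## Disease grouping

Disease ontologies carry many subtype records with no distinct clinical
meaning. Grouping proceeds in two stages.

**Stage 1, string matching.** A name qualifies as a *seed* when its
normalized form (lowercase, punctuation stripped, whitespace collapsed)
ends with a number, a roman numeral (I–XX; a bounded, testable set), or a
short alphanumeric token, or has "type" as its second-last word. The
qualifying ending is dropped to produce the base phrase. The seed's group
collects names that begin with the base phrase (on a token boundary) and
names whose word bag equals the base phrase's bag regardless of order. Two
ambiguities required decisions:

* "Short alphanumeric token" is implemented as length ≤ 2 containing a
  digit, or a single letter (covers "1", "2a", "x"); the predicate is
  configurable (`max_suffix_len`).
* For the bag comparison, ignored words ("type", "(disease)") *and*
  qualifier tokens are removed from both sides wherever they occur. A
  literal suffix-only strip cannot make "type 1 diabetes mellitus" match
  "diabetes mellitus type 1" — the qualifier is not in suffix position in
  the candidate — so position-independent removal is the only reading
  consistent with order-insensitive matching. A guard refuses any merge
  between names sharing no normalized token.

The transitive closure of matches (union-find) yields the partition;
singleton groups keep their original name, merged groups take the shortest
member name unless a review assigns one.

**Stage 2, embedding refinement.** Group representatives (the base phrase
when available, else the full name — stabler against subtype suffixes) are
embedded and pairs with cosine similarity at or above 0.98 become merge
proposals. The quantity is treated as cosine *similarity* throughout
(distance = 1 − similarity). The bundled embedder hashes character
trigrams of the padded, normalized name into 512 buckets and L2-normalizes;
it is fully deterministic, needs no weights, and satisfies the embedder
contract (`similarity(s, s) = 1`). A pretrained clinical language model
can be plugged in through the same `embed_names()` interface, but no
weights ship with the package and all tests use the trigram embedder.
Refinement only merges groups; splitting string-matched groups is out of
scope. Proposals are written to a review file
(`proposal_id, group_a, group_b, representatives, similarity, decision,
assigned_name`) — the reproducible replacement for interactive manual
approval; with `require_review = TRUE` only approved proposals merge.

Grouped nodes take a deterministic identifier (member identifiers sorted
and joined by `_`) and a source tag suffix, which makes the full pipeline
idempotent: re-grouping already-grouped output yields the identity
partition.

## Assembly

Cleaning executes a fixed sequence — drop rows with missing endpoints,
drop duplicates, add reverse edges, drop duplicates again, remove
self-loops — and records per-stage counts that must reconcile
(`assembly_report_reconciles()`). Note one consequence of the ordering:
the mirrored copy of a self-loop is removed by the second deduplication
pass, so the self-loop stage count counts each loop once. Connectivity for
the largest-connected-component step ignores relation types and direction
(the graph is one network for this purpose). Ties in component size never
arise in practice but determinism requires a rule: larger edge count, then
the component containing the smallest canonical node key. An empty input
yields an edge-retention fraction of 1 by definition. Both the pre- and
post-component graphs (`kg_raw`, `kg_giant`) are exportable.

## Clinical features

Drug text features are cleaned of bracketed citation tokens
(`[<letter><digits>]`, prefix letters configurable since only one prefix is
attested in the wild); all other bracketed text is preserved. Half-life
fields stating that no data is available are nullified via a configurable
trigger-phrase list (the exact original phrasing is unknowable, so the
default list is documented and editable). Numeric descriptors render to
fixed sentence templates. Clinic-derived disease features arrive as
pre-extracted tables (scraping is out of scope) and are matched to
ontology names by exact and encapsulating matches first, embedding
proposals second, through the same review workflow as grouping. Grouped
disease nodes aggregate features of all member identifiers, so one node
index may legitimately carry several rows of the same feature; features
are never invented, and unmatched records are returned with a reason.

## The proximity test

For a drug–disease pair the test compares the observed shortest-path hop
distance with distances from the drug to `n_permutations` (default 1000)
sampled non-indicated diseases (uniform without replacement; with
replacement only when the candidate pool is smaller than the request).
Decisions where the design was open:

* **Direction** — small p for small observed distance (the drug is
  *closer* than random). p = P(null ≤ observed) with add-one smoothing,
  `p = (1 + #{d_rand ≤ d_obs}) / (n + 1)`, so p is never exactly zero.
* **Direct pairs** — a pair already joined by an indication edge is
  reported with distance 1 and no p-value, and does not count toward the
  Bonferroni multiplicity, which is the number of pairs actually tested.
* **Unreachable null draws** — excluded from the null mean and confidence
  interval and reported as a count (`n_unreachable`); they still enter the
  p-value, where an infinite distance correctly counts as "farther". A
  finite sentinel can be configured instead; an arbitrary default sentinel
  was rejected as uninterpretable.
* **Confidence interval** — normal-theory interval for the *mean* of the
  null distances at `ci_level` (default 0.95); a percentile bootstrap of
  the sampled mean is available via `ci_method = "percentile"`.

Results are tibbles with `tidy()`, `glance()` and `autoplot()` methods.

## The synthetic-fixture generator

`make_mock_resources()` emits miniature files in every consumed format —
OBO ontologies, expression-call and association TSVs, RRF-style concept
tables, a drug XML with interactions and partner tables, identifier
vocabularies, and synthetic clinical-feature CSVs — with planted ground
truth (filter survivor counts, the overlap set, the subtype partition, a
disconnected two-node pocket that the giant component must exclude).
Identifier namespaces mimic real CURIE shapes without using real
identifiers, so parsers and mapping chains are exercised while accidental
reliance on real data is impossible; name material comes from disjoint
syllable pools per entity class so cross-class string collisions cannot
occur by construction. Generation is deterministic: one seed, one
byte-identical bundle, and every planted count is re-derived through the
adapters at generation time (`verify_fixture_bundle()`).

The proximity testbeds plant structure directly: the *calibration* graph
is a caterpillar in which every disease sits at a distinct hop distance
from the drug, making a uniformly drawn indicated disease exchangeable
with the null sample — on such a graph the raw p-value is approximately
uniform and the rejection rate at 0.05 stays inside its exact binomial
band. The *power* graph plants one indicated disease at 2 hops against a
background at 5, where the smallest achievable p (1/1001) is reached
essentially always.

What passing these tests does *not* show: the generator makes no attempt
at realistic degree distributions, ontology depth, annotation sparsity, or
biological plausibility, and the planted subtype families are cleaner than
real nomenclature (real disease names contain abbreviations, punctuation
variants and synonyms that only a stronger embedder would catch). Results
on synthetic bundles therefore validate the *mechanics* — filters,
conservation, rewiring, determinism, calibration — not the scientific
adequacy of any particular real-world build.

## Problem sizes and runtime

The default test and acceptance workloads use bundles of roughly 250
diseases (40 planted families of 3–8 subtypes plus 100 singletons), 60
phenotypes, 60 proteins and 25 drugs; grouping recovery is measured across
seeds with the adjusted Rand index (an independent implementation,
`mclust::adjustedRandIndex`, serves as the oracle), calibration uses 400
exchangeable pairs at 1000 permutations, and power uses 200 replicates.
These sizes were chosen so the complete suite runs on a laptop in about a
minute while every planted property remains sharply testable; all counts
scale through `fixture_spec()`.

## Known limitations

* The in-memory build is desk-scale; there is no streaming or incremental
  assembly, no graph-database backend, and no RDF/OWL export.
* Membership in the overlap set is purely rule-driven; no semantic
  judgment is made about whether a term *should* be a disease.
* The trigram embedder captures surface similarity only; names that are
  synonyms without shared substrings will not be proposed for merging.
* Only the single-source hop-distance proximity statistic is implemented;
  degree-preserving nulls and module-based proximity variants are
  deliberately out of scope.
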