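---
title: "Integrating GWAS summary statistics: models, scores and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating GWAS summary statistics: models, scores and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdmgwas)
```

Genome-wide association studies (GWAS) report statistical associations
between genetic variants — overwhelmingly single-nucleotide polymorphisms
(SNPs) — and phenotypic traits, aggregated over cohorts of individuals.
Public releases of such summary statistics are heterogeneous: the GWAS
Catalog ships a three-file tab-separated dump (`Studies`, `Ancestry`,
`Associations`, joinable on the study accession), while FinnGen publishes a
manifest of *endpoints* (its term for traits) pointing to per-endpoint
variant tables.  `gdmgwas` turns both into one homogeneous representation
and makes their trait descriptions semantically comparable.  The pipeline
has four programmatic phases, each a package module:

1. **Transform** — source rows become Genomic Data Model (GDM) datasets.
2. **Map** — flat metadata becomes relational rows of a GWAS-specific view
   of the Genomic Conceptual Model (GCM).
3. **Enrich** — cohort trait names are linked to ontology terms through a
   scored annotation algorithm and cached in a local knowledge base.
4. **Flatten** — the integrated metadata is written back to GDM files.

Downloading is reduced to local-file ingestion: the readers accept the
files a release dump provides, and a thin command-line wrapper
(`inst/scripts/gdm-pipeline.R`) exposes the phases to shell pipelines.

## The Genomic Data Model

A GDM *dataset* is a collection of *samples*; a sample pairs a region table
with free attribute–value metadata, under a single declared region schema.
The schema has a fixed coordinate part (`chrom`, `start`, `stop`, `strand`)
and a typed variable part.  Files come in pairs sharing the sample-id stem:
`<id>.gdm` (headerless TSV in schema order) and `<id>.gdm.meta` (two-column
TSV; attributes may repeat, and order is preserved).

Both supported sources describe SNPs, so every region is one base pair:
`stop = start + 1`, strand `"*"` (neither source reports strand).  Catalog
coordinates come from `CHR_ID`/`CHR_POS`; when absent, a
`chr<N>:<pos>`-shaped token is parsed from `STRONGEST SNP-RISK ALLELE`
before its first `-`.  Rows yielding neither are *unresolved*: they are
logged and excluded from region files, never invented.  Coordinates are
copied from the sources without rebasing — Catalog positions are 1-based
while BED-style tooling is 0-based half-open, and since neither convention
can be verified from a dump alone, the package documents `stop` as
exclusive-by-convention in the schema file and leaves the numbers alone.
Chromosome tokens are normalized to `chr`-prefixed form so cross-dataset
interval queries agree on naming.

One Catalog *sample* corresponds to one `Studies` row, i.e. one study–trait
entry, because multi-trait studies are split across rows in the dump.  A
consequence worth knowing: a multi-trait accession contributes its full
association set to each of its trait samples.  Whether the upstream sources
de-duplicate such rows is not documented; the package replicates them and
reports the replication, which keeps region counts conserved and auditable.

## The relational GWAS view

The GCM is a star-shaped model around the **Item** (one file of regions).
For GWAS the Item is a study; its publication is a **CaseStudy**; each Item
has exactly one **Cohort** (trait name plus stage-wise case/control/
individual/trio cardinalities) and a Cohort references any number of
**Ancestry** rows — one per cohort partition.  In flat metadata, ancestry
attributes carry 1-based ordinal suffixes (`broad_ancestral_category_1`,
…, `_7` for a seven-ancestry study), and the mapper materializes one
Ancestry row per distinct ordinal.

Mapping is configuration, not code: a rules file maps attribute-name
patterns (with an ordinal capture group for ancestry attributes) to
`table.column` targets under a named transform.  Supporting a new source
means writing a new rules file.  Two rules matching one attribute with
different targets is a load-time error; integer-cast failures store a
missing value with a warning; anything unmatched is preserved verbatim in a
spillover pair table, so mapping never loses information.  The store is a
set of in-memory relational tables exported as portable SQL DDL plus
per-table TSV dumps whose reload reproduces every row.

## The annotation score

The enricher links each distinct trait value to ontology terms.  Raw
values are first parsed: comma-separated expressions split into one parsed
value per segment; each segment is lowercased, trimmed and
whitespace-collapsed.  Tokens keep internal punctuation
(`magnesium:creatinine` is one token) but shed it at their edges
(`Schizophrenia,` matches `schizophrenia`).  No abbreviation expansion is
attempted.

The similarity between a parsed value and a term label is a word-level
global alignment distance, computed by dynamic programming with an
adjacent-transposition extension (the word-level analogue of a
Damerau-style sequence alignment):

| operation                               | cost |
|-----------------------------------------|------|
| matching word                           | 0    |
| swap of two consecutive words           | 0.5  |
| label-only word (insertion)             | 1    |
| query-only word (deletion)              | 2    |
| mismatched word (substitution)          | 2.5  |

The cost ordering makes the algorithm minimize deletions and prefer swaps
to indels or mismatches.  Two conventions are deliberate and anchored by
the bundled exemplar table (`annotation_examples()`): gap costs are
oriented so that an extra *label* word costs 1 (`sneeze` vs `Peroutka
sneeze` gives 8 on a synonym) while a dropped *query* word costs 2
(`anorexia nervosa` vs `Anorexia` gives 8 on a preferred label); and
transpositions apply only to adjacent cross-equal pairs.  The
`match_score` of a candidate is an initial score of 10 (preferred label) or
9 (synonym) minus this distance, so preferred-label matches outrank synonym
matches by construction; ties prefer the preferred-label basis, then the
lexicographically smallest label.

Ontologies are scored by

* `coverage` — the fraction of raw values the ontology annotates (a raw
  value that splits by comma counts as covered if *any* of its parsed
  values is annotated; coverage is deliberately computed over raw, not
  parsed, values so splitting cannot inflate it);
* `acceptance` — an externally supplied community-trust score in `[0, 1]`,
  consumed from configuration (the package does not compute it; the
  recommender services that do are online systems outside its scope);
* `suitability = coverage × (Σ match_scores / number of annotations)`.

Each candidate annotation is finally ranked by

```
annotation_score = match_score × (w_suit × suitability + w_acc × acceptance)
```

The linear-combination weights are not fixed constants of the method: the
package recovers them by least squares from the bundled exemplar table
(`fit_weights()`, `default_annotation_weights()`), which pins them near
`w_suit = 0.08`, `w_acc = 0.20` and reproduces every exemplar
annotation score within ±0.01.  Both weights are configurable.

```{r}
w <- default_annotation_weights()
round(w, 4)
round(annotation_score(10, 4.39, 0.86, w), 2)  # a top-ranked exemplar row
```

## Choosing a small ontology set

One ontology rarely covers all trait values acceptably, so the package
selects an ordered set greedily: ontologies are ranked (by suitability, or
coverage on request); the first annotates every value it can; each
subsequent ontology is offered only the values still unmatched; selection
stops when accumulated coverage reaches the target (default 0.85) or when
no remaining ontology makes progress — the coverage fixed point.  The
stopping rule is exactly "add another ontology while coverage is below the
target": if two ontologies reach only 0.80, a third that contributes new
values is added.  On three-ontology fixtures the greedy result is verified
against exhaustive subset search.

Set-level metrics are computed over the per-value annotations actually
used.  Two aggregation details are under-determined in the general
formulation and were fixed here, with the literal reading documented:
`SetScore` is the mean over *annotated values* of `match_score ×
acceptance` of the annotating ontology (alternatives — averaging over all
values, or over all annotations — change the denominator); and
`SetSuitability` applies the suitability product to the union of used
annotations.

## Enrichment and the knowledge base

Enrichment is knowledge-base-first: a value whose normalized form equals a
cached preferred label or synonym is linked without any term-source query.
Otherwise the configured ontologies are searched (offline, against a JSON
term corpus shaped like ontology-lookup responses; a live HTTP backend can
implement the same two-function interface).  The best candidate is
auto-accepted when its `match_score` is at least 5 — half the
perfect-preferred-label score; lower-scoring values go to a curation queue
with ranked suggestions.  Original trait values are never modified; the
link lives in the companion attribute `trait_name_tid`.

Every linked term is cached with its description, IRI, synonyms,
cross-references and its is_a/part_of neighbourhood up to a configurable
number of ontology levels (default 3, ancestors and descendants), so
subsequent runs and other sources resolve against the cache.  Sharing one
knowledge base across sources makes term ids comparable, which is what
`common_concepts()` exploits to list concepts referenced by datasets of
both sources.  Enrichment is idempotent: rerunning on an enriched store
changes nothing.

## What the fixtures emulate — and what they do not

The generators are pure functions of `(seed, parameters)` and emit
byte-identical output under a fixed seed, together with a JSON ground-truth
manifest of planted counts.  They emulate the *structural* features the
pipeline must survive: multi-ancestry studies (including a seven-ancestry
one), associations with missing coordinates (resolvable and not), FinnGen
endpoints sharing trait strings with Catalog studies, and a term corpus
with preferred labels, synonyms and shallow hierarchies.  They do not
emulate realistic p-value or effect-size distributions, linkage structure,
genome-scale volumes, or the long tail of free-text trait phrasing in real
releases — so green tests certify the algorithms and contracts, not
real-corpus annotation rates.  The default corpus of ~23 terms is
deliberately small; against real ontology services the candidate space is
many orders of magnitude larger and annotation quality depends on ontology
content, not on this package's scoring alone.

Problem sizes used by the test suite were chosen to keep the full run
under a minute while leaving no algorithmic branch unexercised: fixtures of
2–5 studies × 3–6 associations, 150–200-region interval tables checked
against quadratic brute force, and an exhaustive alignment sweep of all
608,400 ordered pairs of token lists up to length 4 over a five-word
alphabet (the sweep canonicalises each pair to its token-equality pattern,
on which the distance provably depends, and memoises the enumeration
oracle per pattern; the dynamic program itself runs on every literal
pair).

## Numerical and tie-break conventions

* Distances are multiples of 0.5; all comparisons are exact in double
  precision (the costs are dyadic rationals).
* Candidate ranking ties break by annotation score, then preferred-label
  basis, then ontology name, then ontology id — determinism for tests.
* Interval semantics are pinned demo-grade: half-open overlap
  (`start < other.stop && stop > other.start`), distance is the gap
  between intervals (0 when overlapping), the closest-join bound is
  strict, and ties go to the leftmost then smallest target.  Engine-grade
  query languages define richer semantics; these operators only demonstrate
  that the homogenized datasets compose positionally.
* Degenerate inputs are values, not crashes: empty datasets, zero-region
  samples, all-punctuation trait values, unresolved coordinates and
  dangling hierarchy references each have a stated behaviour (empty output,
  warning, or curation-queue entry).

## Known limitations

* The coverage/suitability context of a run is the set of values submitted
  in that run, so annotation scores are comparable within a run, not across
  runs with different value sets.
* `acceptance` must be supplied; there is no offline way to derive it.
* The mapper models the GWAS view in detail and stubs the remaining GCM
  views to minimal columns; it is not a full GCM implementation.
* The relational store is in-memory with TSV/DDL export, sized for
  metadata (thousands of rows), not for the region data itself, which
  stays in GDM files.
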