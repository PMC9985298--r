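# gdmgwas

Genome-wide association studies (GWAS) associate genetic variants — mostly
single-nucleotide polymorphisms (SNPs) — with phenotypic traits across
cohorts of individuals. Their summary statistics are published in
source-specific shapes (the GWAS Catalog's three-file `Studies` /
`Ancestry` / `Associations` dump; FinnGen's manifest of per-endpoint
variant tables), which keeps them hard to use alongside other processed
genomic signals. `gdmgwas` is for data engineers and computational
biologists who need those releases in one homogeneous, queryable form:

* **Transform** — source rows become Genomic Data Model (GDM) datasets:
  each study/endpoint is a *sample* pairing a region file (SNPs as 1-bp
  intervals, `stop = start + 1`, strand `*`) with attribute–value metadata.
* **Map** — metadata becomes a relational GWAS view of the Genomic
  Conceptual Model: `Item` (study) — `CaseStudy` (publication) — `Cohort`
  (trait + stage-wise cardinalities) — `Ancestry` (one row per cohort
  partition, from ordinal-suffixed attributes), driven by declarative
  per-source mapping rules.
* **Enrich** — cohort trait names are linked to ontology terms (e.g. EFO,
  NCIT). Similarity is a word-level global alignment distance
  (match 0, adjacent swap 0.5, label-only word 1, query-only word 2,
  mismatch 2.5), subtracted from an initial score of 10 (preferred label)
  or 9 (synonym) to give a `match_score`; candidates are ranked by

  ```
  annotation_score = match_score × (w_suit · suitability + w_acc · acceptance)
  suitability      = coverage × (Σ match_scores / #annotations)
  ```

  with the weights recovered by least squares from a bundled exemplar
  table (they land near `w_suit = 0.08`, `w_acc = 0.20`). Values whose best
  match reaches `match_score ≥ 5` are auto-linked; the rest join a curation
  queue. A greedy pass picks a small ontology set until coverage reaches
  0.85 (or a fixed point), and linked terms are cached in a knowledge base
  (vocabulary/synonyms/xrefs plus is_a/part_of neighbours to depth 3).
* **Flatten** — the integrated, enriched metadata is written back to GDM
  files, leaving region data byte-identical.

Offline fixture generators for both sources and for ontology corpora, and
toy-scale interval operators (`map_count`, `closest_within`), make every
stage testable without downloads.

## Worked example

```r
library(gdmgwas)

dir <- tempfile(); dir.create(dir)
fx <- generate_catalog_fixture(seed = 1, n_studies = 2, n_assoc_per_study = 3,
                               n_ancestries_per_study = 2,
                               frac_missing_chr = 0, dir = dir)
raw <- read_catalog(fx$paths["studies"], fx$paths["ancestry"],
                    fx$paths["associations"])
ds <- transform_catalog(raw)
ds
#> GDM dataset 'gwas_catalog': 2 samples under schema 'gwas_catalog'
head(ds$samples[[1]]$regions, 2)
#>   chrom     start      stop strand strongest_snp_risk_allele reported_genes  p_value
#> 1 chr20 141472931 141472932      *               rs9738071-A          BRCA2 4.05e-08
#> 2  chr3 127660323 127660324      *               rs9504364-G          BRCA2 3.02e-08

store <- map_dataset(ds, default_mapping_rules("gwas_catalog"))
e <- enrich(store, new_knowledge_base(), c("EFO", "NCIT"),
            generate_ontology_fixture(1), c(EFO = 0.95, NCIT = 0.86))
e
#> Enrichment: 2 of 2 cohort trait values linked; 0 queued for curation
e$store$cohort[, c("cohort_id", "trait_name", "trait_name_tid")]
#>   cohort_id trait_name trait_name_tid
#> 1         1     asthma              1
#> 2         2     stroke              2
```

Every SNP became a 1-bp region with the association attributes copied
verbatim; both fixture traits matched a preferred label exactly
(`match_score` 10) and were auto-linked to knowledge-base terms 1 and 2
(EFO_0000270 *asthma*, EFO_0000712 *stroke*). A partial match shows the
scoring at work — a synonym hit one mismatch away scores 9 − 2.5:

```r
match_score("event free survival time",
            term_record("EFO", "EFO_0004919", "metastasis free survival",
                        synonyms = "metastasis free survival time"))
#> 'event free survival time' -> EFO EFO_0004919
#>   ('metastasis free survival time', synonym): match 6.5 (S)
```

`flatten(e$store, ds, out_dir)` then rewrites the metadata files with the
mapped (`cohort.trait_name`, `ancestry.broad_ancestral_category_1`, ...)
and annotation (`cohort.trait_name_tid`, ...) pairs appended.

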