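Package: gdmgwas
Title: Integration of GWAS Summary Statistics into a Genomic Data Model
    Repository with Ontology-Based Trait Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms GWAS Catalog style three-file dumps and FinnGen style
    manifest plus summary-statistics releases into Genomic Data Model (GDM)
    datasets (paired region/metadata files under a declared region schema),
    maps the attribute-value metadata into an extended Genomic Conceptual
    Model relational view (Item, CaseStudy, Cohort, Ancestry), semantically
    enriches phenotypic trait names against ontology term corpora using a
    word-level alignment distance with match, suitability and annotation
    scores, selects small ontology sets greedily under a coverage target,
    populates a local knowledge base (vocabulary, synonyms, references,
    relationships), and flattens the integrated metadata back to GDM files.
    Includes deterministic fixture generators for both sources and for
    ontology corpora, and toy-scale interval map/closest queries for
    cross-dataset demonstrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    GenomicRanges,
    IRanges,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
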