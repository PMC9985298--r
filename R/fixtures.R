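#' Deterministic source-shaped fixture generators
#'
#' Pure functions of `(seed, parameters)` that emit structurally realistic
#' GWAS Catalog dumps, FinnGen releases and ontology term corpora, plus a
#' JSON ground-truth manifest of planted counts so tests never re-derive
#' expectations by parsing.  Statistical realism (effect sizes, p-value
#' distributions) is out of scope; structural realism (multi-ancestry
#' studies, missing coordinates, shared traits across sources) is the
#' point.
#'
#' @name fixtures
NULL

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

fixture_trait_pool <- function() {
  c("asthma", "stroke", "anxiety", "appendicitis", "diverticulitis",
    "survival time", "bipolar disorder", "calcium measurement",
    "autoimmune disease", "creatinine measurement", "anorexia nervosa",
    "response to vancomycin", "magnesium:creatinine ratio measurement",
    "event free survival time", "sneeze")
}

write_fixture_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Generate a GWAS Catalog style three-file dump
#'
#' @param seed Integer seed; same seed and parameters give byte-identical
#'   files.
#' @param n_studies Number of study-trait entries.
#' @param n_assoc_per_study Associations per study.
#' @param n_ancestries_per_study Ancestry rows per study; scalar or vector
#'   of length `n_studies` (to plant e.g. a seven-ancestry study).
#' @param frac_missing_chr Fraction (of all associations) written without
#'   `CHR_ID`/`CHR_POS`; exactly `round(frac * n)` rows.  These carry a
#'   `chr<N>:<pos>`-shaped risk allele and stay resolvable, except for
#' @param frac_unresolvable that fraction of the missing-coordinate rows,
#'   which get an `rs...`-style allele and cannot be resolved.
#' @param dir Output directory.
#' @return Invisible list with `paths` (studies, ancestry, associations,
#'   ground_truth) and `truth` (the planted counts, also written as JSON).
#' @export
generate_catalog_fixture <- function(seed, n_studies, n_assoc_per_study,
                                     n_ancestries_per_study,
                                     frac_missing_chr, dir,
                                     frac_unresolvable = 0) {
  stopifnot(n_studies >= 0, n_assoc_per_study >= 0,
            frac_missing_chr >= 0, frac_missing_chr <= 1,
            frac_unresolvable >= 0, frac_unresolvable <= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n_anc <- rep_len(n_ancestries_per_study, max(n_studies, 1L))
  with_seed(seed, {
    pool <- fixture_trait_pool()
    accession <- sprintf("GCST%06d", seq_len(n_studies) + 900000L)
    trait <- pool[(seq_len(n_studies) - 1L) %% length(pool) + 1L]
    pubmed <- as.character(sample(20000000:35000000, max(n_studies, 1L)))[seq_len(n_studies)]
    init_n <- sample(500:50000, max(n_studies, 1L), replace = TRUE)[seq_len(n_studies)]
    repl_n <- sample(0:20000, max(n_studies, 1L), replace = TRUE)[seq_len(n_studies)]
    studies <- data.frame(
      check.names = FALSE, stringsAsFactors = FALSE,
      `STUDY ACCESSION` = accession, `DISEASE/TRAIT` = trait,
      `PUBMEDID` = pubmed, `INITIAL SAMPLE SIZE` = init_n,
      `REPLICATION SAMPLE SIZE` = repl_n,
      `DATE ADDED TO CATALOG` = rep("2021-05-06", n_studies))

    categories <- c("European", "Asian unspecified", "African",
                    "Hispanic or Latin American", "East Asian")
    countries <- c("Finland", "U.K.", "U.S.", "Japan", "China", "Germany")
    anc_rows <- list()
    for (i in seq_len(n_studies)) {
      for (k in seq_len(n_anc[i])) {
        anc_rows[[length(anc_rows) + 1L]] <- data.frame(
          check.names = FALSE, stringsAsFactors = FALSE,
          `STUDY ACCESSION` = accession[i],
          `STAGE` = if (k == 1L) "initial" else
            sample(c("initial", "replication"), 1L),
          `NUMBER OF INDIVIDUALS` = sample(100:20000, 1L),
          `BROAD ANCESTRAL CATEGORY` = sample(categories, 1L),
          `COUNTRY OF ORIGIN` = sample(countries, 1L),
          `COUNTRY OF RECRUITMENT` = sample(countries, 1L))
      }
    }
    ancestry <- if (length(anc_rows)) do.call(rbind, anc_rows) else
      data.frame(check.names = FALSE, `STUDY ACCESSION` = character(),
                 `STAGE` = character(), `NUMBER OF INDIVIDUALS` = integer(),
                 `BROAD ANCESTRAL CATEGORY` = character(),
                 `COUNTRY OF ORIGIN` = character(),
                 `COUNTRY OF RECRUITMENT` = character())

    n_assoc <- n_studies * n_assoc_per_study
    chr <- as.character(sample(1:22, max(n_assoc, 1L), replace = TRUE))[seq_len(n_assoc)]
    pos <- sample(1e4:2e8, max(n_assoc, 1L))[seq_len(n_assoc)]
    allele_base <- paste0(sample(c("A", "C", "G", "T"), max(n_assoc, 1L),
                                 replace = TRUE))[seq_len(n_assoc)]
    rsid <- if (n_assoc) paste0("rs", sample(1e6:1e7, n_assoc)) else character()
    associations <- data.frame(
      check.names = FALSE, stringsAsFactors = FALSE,
      `STUDY ACCESSION` = rep(accession, each = n_assoc_per_study),
      `CHR_ID` = chr, `CHR_POS` = as.character(pos),
      `STRONGEST SNP-RISK ALLELE` = paste0(rsid, rep("-", n_assoc),
                                           allele_base),
      `REPORTED GENE(S)` = sample(c("BRCA2", "IL21R", "APOE", "TCF7L2", "NR"),
                                  max(n_assoc, 1L), replace = TRUE)[seq_len(n_assoc)],
      `P-VALUE` = signif(stats::runif(max(n_assoc, 1L), 1e-30, 5e-8),
                         3)[seq_len(n_assoc)])
    n_missing <- round(frac_missing_chr * n_assoc)
    missing_idx <- if (n_missing > 0) sort(sample(seq_len(n_assoc), n_missing))
      else integer()
    n_unres <- round(frac_unresolvable * n_missing)
    unres_idx <- if (n_unres > 0) missing_idx[seq_len(n_unres)] else integer()
    if (n_missing > 0) {
      associations$`CHR_ID`[missing_idx] <- ""
      associations$`CHR_POS`[missing_idx] <- ""
      resolvable_missing <- setdiff(missing_idx, unres_idx)
      associations$`STRONGEST SNP-RISK ALLELE`[resolvable_missing] <-
        paste0("chr", chr[resolvable_missing], ":", pos[resolvable_missing],
               "-", allele_base[resolvable_missing])
    }

    paths <- c(
      studies = write_fixture_tsv(studies, file.path(dir, "studies.tsv")),
      ancestry = write_fixture_tsv(ancestry, file.path(dir, "ancestry.tsv")),
      associations = write_fixture_tsv(associations,
                                       file.path(dir, "associations.tsv")))
    truth <- list(n_studies = n_studies, n_associations = n_assoc,
                  n_missing_chr = n_missing, n_unresolvable = n_unres,
                  n_resolvable = n_assoc - n_unres,
                  ancestries_per_study = stats::setNames(as.list(n_anc[seq_len(n_studies)]),
                                                         accession),
                  traits = stats::setNames(as.list(trait), accession))
    truth_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
    invisible(list(paths = c(paths, ground_truth = truth_path), truth = truth))
  })
}

#' Generate a FinnGen style manifest plus summary-statistics files
#'
#' @param seed Integer seed.
#' @param n_endpoints Number of endpoints in the manifest.
#' @param n_variants Variant rows per endpoint (scalar or vector).
#' @param shared_trait_labels Trait labels assigned to the first endpoints,
#'   to plant traits shared with a Catalog fixture (exercises
#'   [common_concepts()]).
#' @param dir Output directory.
#' @return Invisible list with `paths` (`manifest`, `ground_truth`, plus the
#'   per-endpoint files) and `truth`.
#' @export
generate_finngen_fixture <- function(seed, n_endpoints, n_variants,
                                     shared_trait_labels = character(),
                                     dir) {
  stopifnot(n_endpoints >= 0, length(shared_trait_labels) <= n_endpoints)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n_var <- rep_len(n_variants, max(n_endpoints, 1L))
  with_seed(seed, {
    pool <- rev(fixture_trait_pool())
    phenocode <- sprintf("FG_ENDPOINT_%03d", seq_len(n_endpoints))
    trait <- pool[(seq_len(n_endpoints) - 1L) %% length(pool) + 1L]
    if (length(shared_trait_labels)) {
      trait[seq_along(shared_trait_labels)] <- shared_trait_labels
    }
    files <- if (n_endpoints) paste0(phenocode, ".tsv") else character()
    manifest <- data.frame(phenocode = phenocode, phenostring = trait,
                           file = files, stringsAsFactors = FALSE)
    manifest_path <- write_fixture_tsv(manifest,
                                       file.path(dir, "manifest.tsv"))
    endpoint_paths <- character(n_endpoints)
    for (i in seq_len(n_endpoints)) {
      n <- n_var[i]
      bases <- c("A", "C", "G", "T")
      vdf <- data.frame(
        check.names = FALSE, stringsAsFactors = FALSE,
        `#chrom` = as.character(sample(1:22, max(n, 1L),
                                       replace = TRUE))[seq_len(n)],
        pos = sample(1e4:2e8, max(n, 1L))[seq_len(n)],
        ref = sample(bases, max(n, 1L), replace = TRUE)[seq_len(n)],
        alt = sample(bases, max(n, 1L), replace = TRUE)[seq_len(n)],
        rsids = if (n) paste0("rs", sample(1e6:1e7, n)) else character(),
        pval = signif(stats::runif(max(n, 1L), 1e-20, 1), 3)[seq_len(n)],
        beta = round(stats::rnorm(max(n, 1L), 0, 0.2), 4)[seq_len(n)],
        sebeta = round(stats::runif(max(n, 1L), 0.01, 0.1), 4)[seq_len(n)])
      endpoint_paths[i] <- write_fixture_tsv(vdf, file.path(dir, files[i]))
    }
    truth <- list(n_endpoints = n_endpoints,
                  variants_per_endpoint = stats::setNames(as.list(n_var[seq_len(n_endpoints)]),
                                                          phenocode),
                  traits = stats::setNames(as.list(trait), phenocode))
    truth_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
    invisible(list(paths = c(manifest = manifest_path,
                             ground_truth = truth_path,
                             stats::setNames(endpoint_paths, phenocode)),
                   truth = truth))
  })
}

#' Default ontology term corpus for offline enrichment
#'
#' A small synthetic corpus of term records covering the traits emitted by
#' the source fixture generators, including the exemplar terms of the
#' bundled annotation table (Creatinine Measurement, Anorexia, metastasis
#' free survival, Peroutka sneeze, Appendicitis, ...), with synonyms and
#' shallow is_a hierarchies.
#'
#' @return List of [term_record()]s.
#' @export
default_term_corpus <- function() {
  pl <- function(...) list(...)
  lk <- function(onto, id, kind = "is_a") {
    list(ontology = onto, ontology_id = id, kind = kind)
  }
  list(
    term_record("NCIT", "NCIT_C64547", "Creatinine Measurement",
                synonyms = c("Creatinine", "Creatinine Level"),
                description = "Measurement of creatinine in a biological specimen.",
                iri = "http://purl.obolibrary.org/obo/NCIT_C64547",
                xrefs = "UMLS:C0201975",
                parents = pl(lk("NCIT", "NCIT_C25294")),
                children = pl(lk("NCIT", "NCIT_C61048"))),
    term_record("NCIT", "NCIT_C61048", "Urine Creatinine Measurement",
                synonyms = "Urine Creatinine Measurement",
                parents = pl(lk("NCIT", "NCIT_C64547"))),
    term_record("NCIT", "NCIT_C25294", "Laboratory Procedure",
                parents = pl(lk("NCIT", "NCIT_C25218")),
                children = pl(lk("NCIT", "NCIT_C64547"))),
    term_record("NCIT", "NCIT_C25218", "Intervention or Procedure",
                parents = pl(lk("NCIT", "NCIT_C43431"))),
    term_record("NCIT", "NCIT_C43431", "Activity",
                parents = pl(lk("NCIT", "NCIT_C1908"))),
    term_record("NCIT", "NCIT_C1908", "Thing"),
    term_record("NCIT", "NCIT_C35145", "Appendicitis",
                synonyms = "appendicitis",
                description = "Acute or chronic inflammation of the appendix.",
                parents = pl(lk("NCIT", "NCIT_C3138"))),
    term_record("NCIT", "NCIT_C3138", "Inflammation",
                parents = pl(lk("NCIT", "NCIT_C2991")),
                children = pl(lk("NCIT", "NCIT_C35145"))),
    term_record("NCIT", "NCIT_C2991", "Disease or Disorder"),
    term_record("NCIT", "NCIT_C76312", "Vancomycin Resistant Enterococcus",
                synonyms = c("Vancomycin-Resistant Enterococcus", "VRE")),
    term_record("NCIT", "NCIT_C139219", "Lean Body Mass to Total Body Mass Ratio",
                synonyms = "Lean Body Mass to Total Body Mass Ratio"),
    term_record("EFO", "EFO_0000270", "asthma",
                synonyms = c("bronchial asthma", "Asthma unspecified")),
    term_record("EFO", "EFO_0000712", "stroke",
                synonyms = c("cerebral accident", "apoplexy")),
    term_record("EFO", "EFO_0005230", "anxiety"),
    term_record("EFO", "EFO_1001460", "diverticulitis",
                synonyms = "digestive tract diverticulum inflammation"),
    term_record("EFO", "EFO_0000714", "survival time",
                synonyms = c("survival", "time of survival"),
                children = pl(lk("EFO", "EFO_0004919"))),
    term_record("EFO", "EFO_0004919", "metastasis free survival",
                synonyms = "metastasis free survival time",
                parents = pl(lk("EFO", "EFO_0000714"))),
    term_record("EFO", "EFO_0000289", "bipolar disorder",
                synonyms = c("bipolar depression", "manic disorder")),
    term_record("EFO", "EFO_0004838", "calcium measurement",
                synonyms = "calcium levels"),
    term_record("EFO", "EFO_0005140", "autoimmune disease",
                synonyms = "autoimmunity"),
    term_record("EFO", "EFO_0007887",
                "autosomal dominant compelling helio-ophthalmic outburst syndrome",
                synonyms = c("photic sneeze reflex", "Peroutka sneeze")),
    term_record("EFO", "EFO_0007635", "concentration dose ratio",
                synonyms = "CDR measurement"),
    term_record("HP", "HP_0002039", "Anorexia", synonyms = "Anorexia"))
}

#' Generate (and optionally write) an ontology fixture corpus
#'
#' @param seed Integer seed (kept for generator-API uniformity; the corpus
#'   content is fully determined by `terms_spec`).
#' @param terms_spec List of [term_record()]s; default
#'   [default_term_corpus()].  Duplicate term ids are an error.
#' @param path Optional JSON output path.
#' @return A [term_source_fixture()] over the corpus, invisibly when `path`
#'   is given.
#' @export
generate_ontology_fixture <- function(seed = 1L, terms_spec = NULL,
                                      path = NULL) {
  if (is.null(terms_spec)) terms_spec <- default_term_corpus()
  src <- term_source_fixture(terms_spec)
  if (!is.null(path)) {
    write_term_corpus(terms_spec, path)
    return(invisible(src))
  }
  src
}
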