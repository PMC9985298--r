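assoc_df <- function(accession, chr_id, chr_pos, allele,
                     genes = "NR", p = 1e-9) {
  data.frame(study_accession = accession, chr_id = chr_id, chr_pos = chr_pos,
             strongest_snp_risk_allele = allele, reported_genes = genes,
             p_value = p, stringsAsFactors = FALSE)
}

test_that("coordinates resolve from CHR_ID, then the risk-allele token", {
  rows <- assoc_df("G", c("13", "", ""), c(32315473L, NA, NA),
                   c("rs11571833-T", "chr6:29623739-T", "rs123-A"))
  got <- resolve_catalog_coordinates(rows)
  expect_equal(got$chrom, c("chr13", "chr6", NA))
  expect_equal(got$start, c(32315473L, 29623739L, NA))
  expect_equal(got$stop, c(32315474L, 29623740L, NA))
  expect_equal(got$strand, c("*", "*", NA))
  expect_equal(got$resolved, c(TRUE, TRUE, FALSE))
})

test_that("already chr-prefixed and sex chromosomes normalize consistently", {
  rows <- assoc_df("G", c("chrX", "X"), c(5L, 5L), c("rs1-A", "rs2-A"))
  expect_equal(resolve_catalog_coordinates(rows)$chrom, c("chrX", "chrX"))
})

test_that("catalog samples carry the resolvable regions of their accession", {
  studies <- data.frame(study_accession = "GCST1", disease_trait = "asthma",
                        pubmed_id = "1", stringsAsFactors = FALSE)
  ancestries <- data.frame(study_accession = character(), stage = character(),
                           number_of_individuals = integer(),
                           broad_ancestral_category = character(),
                           country_of_origin = character(),
                           country_of_recruitment = character())
  assoc <- assoc_df("GCST1", c("1", "2", ""), c(100L, 200L, NA),
                    c("rs1-A", "rs2-A", "rs3-A"))
  ds <- suppressMessages(transform_catalog(studies = studies,
                                           ancestries = ancestries,
                                           associations = assoc))
  expect_length(ds$samples, 1)
  r <- ds$samples[["GCST1"]]$regions
  expect_equal(nrow(r), 2)
  expect_equal(r$stop, r$start + 1L)
  expect_true(all(r$strand == "*"))
  expect_equal(r$p_value, c(1e-9, 1e-9))
})

test_that("ancestry metadata is suffixed _1.._n in file order", {
  studies <- data.frame(study_accession = "GCST007269",
                        disease_trait = "eczema", pubmed_id = "2",
                        stringsAsFactors = FALSE)
  cats <- c("European", "Asian unspecified", "African", "European",
            "East Asian", "African", "European")
  ancestries <- data.frame(study_accession = "GCST007269", stage = "initial",
                           number_of_individuals = 100L + seq_len(7),
                           broad_ancestral_category = cats,
                           country_of_origin = "NR",
                           country_of_recruitment = "NR",
                           stringsAsFactors = FALSE)
  ds <- suppressWarnings(transform_catalog(
    studies = studies, ancestries = ancestries,
    associations = assoc_df(character(), character(), integer(), character(),
                            genes = character(), p = numeric())))
  meta <- ds$samples[[1]]$metadata
  keys <- paste0("broad_ancestral_category_", 1:7)
  expect_true(all(keys %in% meta$attribute))
  expect_equal(meta$value[match(keys, meta$attribute)], cats)
  expect_false("broad_ancestral_category_8" %in% meta$attribute)
})

test_that("zero-resolvable studies emit an empty sample with a warning", {
  studies <- data.frame(study_accession = "GCST2", disease_trait = "stroke",
                        pubmed_id = "3", stringsAsFactors = FALSE)
  assoc <- assoc_df("GCST2", "", NA, "rs9-A")
  expect_warning(
    ds <- suppressMessages(transform_catalog(
      studies = studies,
      ancestries = data.frame(study_accession = character(),
                              stage = character(),
                              number_of_individuals = integer(),
                              broad_ancestral_category = character(),
                              country_of_origin = character(),
                              country_of_recruitment = character()),
      associations = assoc)),
    "no resolvable")
  expect_equal(nrow(ds$samples[[1]]$regions), 0)
})

test_that("region count conservation holds on a generated dump", {
  dir <- withr::local_tempdir()
  fx <- generate_catalog_fixture(11, 4, 6, 2, 0.25, dir,
                                 frac_unresolvable = 0.5)
  got <- read_catalog(fx$paths["studies"], fx$paths["ancestry"],
                      fx$paths["associations"])
  ds <- suppressMessages(transform_catalog(got))
  expect_length(ds$samples, fx$truth$n_studies)
  total_regions <- sum(vapply(ds$samples, function(s) nrow(s$regions),
                              integer(1)))
  expect_equal(total_regions, fx$truth$n_resolvable)
  for (s in ds$samples) {
    if (nrow(s$regions)) {
      expect_equal(s$regions$stop, s$regions$start + 1L)
      expect_true(all(s$regions$strand == "*"))
    }
  }
})

test_that("finngen variants become 1-bp regions with attributes copied", {
  entries <- list(list(
    endpoint = list(endpoint_name = "FG1", trait_label = "appendicitis",
                    summary_path = "x"),
    variants = data.frame(chrom = c("7", "2", "X"), pos = c(100L, 5L, 9L),
                          ref = "A", alt = "G", rsid = c("rs1", "rs2", "rs3"),
                          pval = c(0.1, 0.2, 0.3), stringsAsFactors = FALSE)))
  ds <- transform_finngen(entries)
  r <- ds$samples[["FG1"]]$regions
  expect_equal(r$chrom, c("chr7", "chr2", "chrX"))
  expect_equal(r[1, c("start", "stop", "strand")],
               data.frame(start = 100L, stop = 101L, strand = "*"),
               ignore_attr = TRUE)
  expect_equal(r$rsid, c("rs1", "rs2", "rs3"))
  meta <- ds$samples[["FG1"]]$metadata
  expect_equal(meta$value[meta$attribute == "trait_name"], "appendicitis")
})

test_that("finngen edge cases: empty endpoints and nonpositive positions", {
  empty <- list(list(endpoint = list(endpoint_name = "E0", trait_label = "x",
                                     summary_path = "p"),
                     variants = data.frame(chrom = character(),
                                           pos = integer(), ref = character(),
                                           alt = character(),
                                           rsid = character(),
                                           pval = numeric())))
  expect_equal(nrow(transform_finngen(empty)$samples[["E0"]]$regions), 0)

  badpos <- list(list(endpoint = list(endpoint_name = "E1", trait_label = "x",
                                      summary_path = "p"),
                      variants = data.frame(chrom = c("1", "1"),
                                            pos = c(0L, 50L), ref = "A",
                                            alt = "C", rsid = "rs",
                                            pval = 0.5,
                                            stringsAsFactors = FALSE)))
  expect_warning(ds <- transform_finngen(badpos), "nonpositive")
  expect_equal(ds$samples[["E1"]]$regions$start, 50L)
})
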