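mapped_fixture <- function(seed = 5) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  fx <- generate_catalog_fixture(seed, 3, 4, c(2, 7, 1), 0, dir)
  got <- read_catalog(fx$paths["studies"], fx$paths["ancestry"],
                      fx$paths["associations"])
  ds <- suppressMessages(transform_catalog(got))
  list(store = map_dataset(ds, default_mapping_rules("gwas_catalog")),
       dataset = ds, truth = fx$truth)
}

test_that("mapper cardinalities: one item and cohort per sample, one ancestry
           row per planted ordinal", {
  m <- mapped_fixture()
  expect_equal(nrow(m$store$item), 3)
  expect_equal(nrow(m$store$cohort), 3)
  expect_equal(nrow(m$store$ancestry),
               sum(unlist(m$truth$ancestries_per_study)))
  # the seven-ancestry study references seven rows of one cohort
  acc7 <- names(which(unlist(m$truth$ancestries_per_study) == 7))
  item7 <- m$store$item$item_id[m$store$item$source_id == acc7]
  coh7 <- m$store$cohort$cohort_id[m$store$cohort$item_id == item7]
  anc7 <- m$store$ancestry[m$store$ancestry$cohort_id == coh7, ]
  expect_equal(sort(anc7$ordinal), 1:7)
  expect_no_error(check_store(m$store))
})

test_that("cohort rows carry the trait and integer-cast sample sizes", {
  m <- mapped_fixture()
  expect_equal(m$store$cohort$trait_name,
               unname(unlist(m$truth$traits))[match(m$store$item$source_id,
                                                    names(m$truth$traits))])
  expect_type(m$store$cohort$initial_individuals, "integer")
  expect_false(any(is.na(m$store$cohort$initial_individuals)))
})

test_that("unmatched attributes spill over verbatim", {
  m <- mapped_fixture()
  spill <- m$store$pair
  expect_true(all(spill$attribute == "date_added_to_catalog"))
  expect_equal(nrow(spill), 3)
})

test_that("samples without ancestry attributes map to zero ancestry rows", {
  schema <- region_schema("bare")
  s <- gdm_sample("X1", empty_regions(schema),
                  data.frame(attribute = c("study_accession", "disease_trait"),
                             value = c("GCSTX", "stroke")), schema)
  store <- map_dataset(gdm_dataset("d", schema, list(s)),
                       default_mapping_rules("gwas_catalog"))
  expect_equal(nrow(store$item), 1)
  expect_equal(nrow(store$cohort), 1)
  expect_equal(nrow(store$ancestry), 0)
})

test_that("conflicting rules and broken ordinals are load-time errors", {
  schema <- region_schema("bare")
  s <- gdm_sample("X1", empty_regions(schema),
                  data.frame(attribute = "disease_trait", value = "stroke"),
                  schema)
  ds <- gdm_dataset("d", schema, list(s))
  conflict <- rbind(default_mapping_rules("gwas_catalog"),
                    data.frame(pattern = "disease_trait", table = "item",
                               column = "source_id", transform = "identity"))
  expect_error(map_dataset(ds, conflict), "rule conflict")

  s2 <- gdm_sample("X2", empty_regions(schema),
                   data.frame(attribute = "broad_ancestral_category_2",
                              value = "European"), schema)
  expect_error(map_dataset(gdm_dataset("d", schema, list(s2)),
                           default_mapping_rules("gwas_catalog")),
               "not contiguous")

  bad_rule <- data.frame(pattern = "x", table = "nope", column = "y",
                         transform = "identity")
  expect_error(map_dataset(ds, bad_rule), "unknown table")
})

test_that("integer-cast failures warn and store missing", {
  schema <- region_schema("bare")
  s <- gdm_sample("X1", empty_regions(schema),
                  data.frame(attribute = c("disease_trait",
                                           "initial_sample_size"),
                             value = c("stroke", "up to 5,000")), schema)
  expect_warning(
    store <- map_dataset(gdm_dataset("d", schema, list(s)),
                         default_mapping_rules("gwas_catalog")),
    "integer-cast")
  expect_true(is.na(store$cohort$initial_individuals))
})

test_that("export and reload preserve every table row-for-row", {
  m <- mapped_fixture()
  dir <- withr::local_tempdir()
  export_store(m$store, dir)
  expect_true(file.exists(file.path(dir, "gcm_schema.sql")))
  back <- load_store(dir)
  for (tb in names(m$store)) expect_equal(back[[tb]], m$store[[tb]])
  expect_no_error(check_store(back))
})

test_that("empty stores export DDL plus empty dumps", {
  schema <- region_schema("bare")
  store <- map_dataset(gdm_dataset("d", schema, list()),
                       default_mapping_rules("gwas_catalog"))
  dir <- withr::local_tempdir()
  export_store(store, dir)
  ddl <- readLines(file.path(dir, "gcm_schema.sql"))
  expect_true(any(grepl("CREATE TABLE cohort", ddl)))
  back <- load_store(dir)
  expect_equal(nrow(back$item), 0)
})
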