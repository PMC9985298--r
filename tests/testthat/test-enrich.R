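trait_store <- function(traits) {
  schema <- region_schema("bare")
  samples <- lapply(seq_along(traits), function(i) {
    gdm_sample(paste0("S", i), empty_regions(schema),
               data.frame(attribute = c("study_accession", "disease_trait"),
                          value = c(paste0("GCST", i), traits[i])), schema)
  })
  map_dataset(gdm_dataset("d", schema, samples),
              default_mapping_rules("gwas_catalog"))
}

fixture_acceptance <- c(EFO = 0.95, NCIT = 0.86, HP = 0.31)

test_that("values at or above the match threshold are linked, others queued", {
  traits <- c("asthma", "stroke", "anxiety", "diverticulitis",
              "event free survival time", "anorexia nervosa",      # >= 5
              "response to vancomycin",                            # 4
              "other and unspecified",                             # < 5
              "zzz yyy xxx www", "qqq rrr sss ttt")                # no match
  store <- trait_store(traits)
  src <- generate_ontology_fixture(1)
  e <- enrich(store, new_knowledge_base(), c("EFO", "NCIT", "HP"), src,
              fixture_acceptance)
  linked <- !is.na(e$store$cohort$trait_name_tid)
  expect_equal(sum(linked), 6)
  expect_equal(nrow(e$queue), 4)
  expect_setequal(e$queue$trait_name, traits[7:10])
  # below-threshold values still get ranked suggestions
  vanc <- e$queue[e$queue$trait_name == "response to vancomycin", ]
  expect_match(vanc$suggestions, "match=")
  expect_false(grepl("match=[5-9]", vanc$suggestions))
  # original trait values are never modified
  expect_equal(e$store$cohort$trait_name, traits)
})

test_that("knowledge-base hits complete the procedure without a search", {
  store <- trait_store("creatinine measurement")
  kb <- populate_kb(new_knowledge_base(),
                    term_record("NCIT", "NCIT_C64547", "Creatinine Measurement",
                                synonyms = "Creatinine"),
                    term_source_fixture(list()), levels = 0)
  # term source knows nothing: a link can only come from the KB
  e <- enrich(store, kb, c("EFO", "NCIT"), term_source_fixture(list()),
              fixture_acceptance)
  expect_equal(e$store$cohort$trait_name_tid, 1L)
  expect_equal(nrow(e$queue), 0)
})

test_that("enrichment is idempotent on an already-enriched store", {
  store <- trait_store(c("asthma", "zzz unknown"))
  src <- generate_ontology_fixture(1)
  e1 <- enrich(store, new_knowledge_base(), c("EFO", "NCIT"), src,
               fixture_acceptance)
  e2 <- enrich(e1$store, e1$kb, c("EFO", "NCIT"), src, fixture_acceptance)
  expect_equal(e2$store, e1$store)
  expect_equal(e2$kb$vocabulary, e1$kb$vocabulary)
})

test_that("auto-linking populates the knowledge base around the used term", {
  store <- trait_store("creatinine measurement")
  src <- generate_ontology_fixture(1)
  e <- enrich(store, new_knowledge_base(), c("EFO", "NCIT"), src,
              fixture_acceptance, kb_depth = 2)
  tid <- e$store$cohort$trait_name_tid
  v <- e$kb$vocabulary
  expect_equal(v$ontology_id[v$tid == tid], "NCIT_C64547")
  # two ancestor levels and the child term are cached alongside
  expect_true(all(c("NCIT_C25294", "NCIT_C25218", "NCIT_C61048") %in%
                    v$ontology_id))
  expect_false("NCIT_C43431" %in% v$ontology_id)   # level 3: beyond depth 2
  expect_gt(nrow(e$kb$relationship), 0)
  expect_no_error(check_store(e$store))
})

test_that("unknown acceptance for a requested ontology is an error", {
  store <- trait_store("asthma")
  expect_error(enrich(store, new_knowledge_base(), c("EFO", "XXO"),
                      generate_ontology_fixture(1), fixture_acceptance),
               "XXO")
})

test_that("common concepts are the tid intersection across sources", {
  a <- data.frame(tid = c(1L, 2L, 3L), sample_id = c("A1", "A2", "A3"))
  b <- data.frame(tid = c(2L, 3L, 9L), sample_id = c("B1", "B1", "B9"))
  got <- common_concepts(list(cat = a, fin = b))
  expect_equal(got$tid, c(2L, 3L))
  expect_equal(got$samples_cat, c("A2", "A3"))

  expect_equal(nrow(common_concepts(list(
    cat = a, fin = data.frame(tid = 99L, sample_id = "x")))), 0)
  same <- common_concepts(list(cat = a, fin = a))
  expect_equal(same$tid, a$tid)
})

test_that("a trait shared across sources yields a common concept end-to-end", {
  dir_c <- withr::local_tempdir()
  dir_f <- withr::local_tempdir()
  fx_c <- generate_catalog_fixture(2, 4, 2, 1, 0, dir_c)  # includes appendicitis
  fx_f <- generate_finngen_fixture(3, 2, 3, "appendicitis", dir_f)
  ds_c <- suppressMessages(transform_catalog(read_catalog(
    fx_c$paths["studies"], fx_c$paths["ancestry"], fx_c$paths["associations"])))
  ds_f <- transform_finngen(read_finngen(fx_f$paths["manifest"], dir_f))
  st_c <- map_dataset(ds_c, default_mapping_rules("gwas_catalog"))
  st_f <- map_dataset(ds_f, default_mapping_rules("finngen"))
  src <- generate_ontology_fixture(1)
  e_c <- enrich(st_c, new_knowledge_base(), c("EFO", "NCIT"), src,
                fixture_acceptance)
  e_f <- enrich(st_f, e_c$kb, c("EFO", "NCIT"), src, fixture_acceptance)
  cc <- common_concepts(list(gwas_catalog = e_c$store, finngen = e_f$store),
                        e_f$kb)
  expect_true("NCIT_C35145" %in% cc$ontology_id)
  row <- cc[cc$ontology_id == "NCIT_C35145", ]
  expect_equal(row$pref_label, "Appendicitis")
  expect_match(row$samples_finngen, "FG_ENDPOINT_001")
})
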