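test_that("match_score picks the best basis and caps at 10 (9 for synonyms)", {
  t_creat <- term_record("NCIT", "NCIT_C64547", "Creatinine Measurement",
                         synonyms = c("Creatinine", "Creatinine Level"))
  c1 <- match_score("creatinine measurement", t_creat)
  expect_equal(c1$match_score, 10)
  expect_equal(c1$basis, "P")

  t_mfs <- term_record("EFO", "EFO_0004919", "metastasis free survival",
                       synonyms = "metastasis free survival time")
  c2 <- match_score("event free survival time", t_mfs)
  expect_equal(c2$match_score, 6.5)
  expect_equal(c2$basis, "S")

  # any value equalling a pref_label verbatim scores 10
  t <- term_record("EFO", "X", "some exact thing")
  expect_equal(match_score("some exact thing", t)$match_score, 10)

  # synonym-based scores never exceed 9; none exceed 10
  for (term in default_term_corpus()) {
    cand <- match_score("asthma", term)
    expect_lte(cand$match_score, 10)
    if (cand$basis == "S") expect_lte(cand$match_score, 9)
  }
})

test_that("ontology coverage and suitability follow the product formula", {
  ann <- data.frame(ontology = c("EFO", "EFO"), raw = c("a", "b"),
                    match_score = c(10, 9))
  got <- ontology_scores(ann, 4, c(EFO = 0.5))
  expect_equal(got$coverage, 0.5)
  expect_equal(got$suitability, 0.5 * 9.5)   # = 4.75

  # all values matched on pref labels: coverage 1, suitability 10
  full <- data.frame(ontology = "NCIT", raw = c("a", "b"),
                     match_score = c(10, 10))
  got <- ontology_scores(full, 2, c(NCIT = 0.9))
  expect_equal(got$coverage, 1)
  expect_equal(got$suitability, 10)

  # no annotations: nothing to score
  none <- ontology_scores(full[0, ], 2, c(NCIT = 0.9))
  expect_equal(nrow(none), 0)

  expect_error(ontology_scores(full, 2, c(EFO = 0.9)), "acceptance")
})

test_that("annotation scores reproduce the exemplar table rows", {
  w <- default_annotation_weights()
  expect_equal(annotation_score(10, 4.39, 0.86, w), 5.23, tolerance = 0.01 / 5.23)
  expect_equal(annotation_score(10, 0.10, 0.25, w), 0.58, tolerance = 0.01 / 0.58)
  expect_equal(annotation_score(0, 3.4, 0.32, w), 0)
  expect_error(annotation_score(5, 1, 1, c(-0.1, 0.2)), "nonnegative")
})

test_that("least-squares weight recovery is exact on consistent systems", {
  rows <- data.frame(match_score = c(10, 8),
                     suitability = c(4, 1), acceptance = c(0.5, 0.9))
  rows$annotation_score <- rows$match_score *
    (0.08 * rows$suitability + 0.2 * rows$acceptance)
  w <- fit_weights(rows)
  expect_equal(unname(w), c(0.08, 0.2), tolerance = 1e-10)

  expect_error(fit_weights(rows[1, ]), "linearly independent")
  collinear <- data.frame(match_score = c(10, 5), suitability = c(2, 2),
                          acceptance = c(1, 1), annotation_score = c(3, 1.5))
  expect_error(fit_weights(collinear), "linearly independent")
})

test_that("greedy ontology-set selection matches exhaustive subset search", {
  values <- paste0("v", 1:10)
  acc <- c(A = 0.9, B = 0.8, C = 0.7)

  # two ontologies suffice: greedy must pick exactly a minimal covering pair
  ann <- sel_fixture(list(A = paste0("v", 1:5), B = paste0("v", 4:9),
                          C = paste0("v", 1:3)))
  got <- select_ontology_set(values, ann, acc, coverage_target = 0.85)
  expect_equal(got$set_coverage, 0.9)
  ex <- exhaustive_best_set(values, ann, 0.85)
  expect_equal(length(got$ontologies), ex$size)
  expect_true(any(vapply(ex$sets, setequal, logical(1), got$ontologies)))

  # the third ontology is needed to reach the target
  ann3 <- sel_fixture(list(A = paste0("v", 1:5), B = paste0("v", 6:8),
                           C = "v9"))
  got3 <- select_ontology_set(values, ann3, acc, coverage_target = 0.85)
  expect_equal(length(got3$ontologies), 3)
  expect_equal(got3$set_coverage, 0.9)
  ex3 <- exhaustive_best_set(values, ann3, 0.85)
  expect_equal(length(got3$ontologies), ex3$size)
})

test_that("selection coverage is monotone and stops at the fixed point", {
  values <- paste0("v", 1:10)
  acc <- c(A = 0.9, B = 0.8, C = 0.7)
  ann <- sel_fixture(list(A = paste0("v", 1:5), B = paste0("v", 4:9),
                          C = paste0("v", 1:3)))
  # prefix coverages are nondecreasing
  prev <- 0
  got <- select_ontology_set(values, ann, acc, coverage_target = 1)
  for (k in seq_along(got$ontologies)) {
    sub <- ann[ann$ontology %in% got$ontologies[seq_len(k)], ]
    cov <- length(unique(sub$raw)) / length(values)
    expect_gte(cov, prev)
    prev <- cov
  }
  # unreachable target: stops when no ontology makes progress (0.9 here)
  expect_equal(got$set_coverage, 0.9)

  # one ontology already over target: singleton set
  one <- select_ontology_set(values, sel_fixture(list(A = paste0("v", 1:9))),
                             acc, coverage_target = 0.85)
  expect_equal(one$ontologies, "A")

  # target zero: the first ontology is the fixed point
  zero <- select_ontology_set(values, ann, acc, coverage_target = 0)
  expect_length(zero$ontologies, 1)

  expect_error(select_ontology_set(values, ann[0, ], acc, 0.85),
               "no ontologies")
})

test_that("set metrics follow the stated aggregation over used annotations", {
  values <- c("a", "b", "c", "d")
  ann <- rbind(data.frame(ontology = "A", raw = c("a", "b"),
                          match_score = c(10, 8)),
               data.frame(ontology = "B", raw = c("b", "c"),
                          match_score = c(9, 9)))
  acc <- c(A = 0.5, B = 0.25)
  got <- select_ontology_set(values, ann, acc, coverage_target = 0.99)
  # A first (suitability 0.5*9 = 4.5 vs B 0.5*9 = 4.5, tie -> name order);
  # A covers a,b; B adds c
  expect_equal(got$ontologies, c("A", "B"))
  expect_equal(got$set_coverage, 0.75)
  # used annotations: a->A(10), b->A(8), c->B(9)
  expect_equal(got$set_score, mean(c(10 * 0.5, 8 * 0.5, 9 * 0.25)))
  expect_equal(got$set_suitability, 0.75 * (10 + 8 + 9) / 3)
})
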