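#' Mapping GDM metadata into the extended GCM relational view
#'
#' The Genomic Conceptual Model (GCM) is a star-shaped relational model
#' around the Item entity (one file of genomic regions).  For GWAS the Item
#' is a study; the publication maps to CaseStudy; each study has exactly one
#' Cohort (the case/control population, with its trait and stage-wise
#' cardinalities) and a Cohort can reference many Ancestry rows (one per
#' cohort partition, with ordinal suffixes `_1.._n` in the flat metadata).
#'
#' Mapping is driven by declarative rules -- data, not code -- so a new
#' source needs only a new rules file: each rule maps an attribute-name
#' pattern (with an optional ordinal capture group for Ancestry) to a
#' `table.column` target under a named value transform.
#'
#' @name gcm_mapper
NULL

gcm_table_spec <- function() {
  list(
    item = c(item_id = "integer", sample_id = "character",
             source_id = "character", dataset_name = "character",
             case_study_id = "integer"),
    case_study = c(case_study_id = "integer", pubmed_id = "character",
                   source_site = "character"),
    cohort = c(cohort_id = "integer", item_id = "integer",
               trait_name = "character", trait_name_tid = "integer",
               initial_cases = "integer", initial_controls = "integer",
               initial_individuals = "integer", initial_trios = "integer",
               replication_cases = "integer", replication_controls = "integer",
               replication_individuals = "integer",
               replication_trios = "integer"),
    ancestry = c(ancestry_id = "integer", cohort_id = "integer",
                 ordinal = "integer", broad_ancestral_category = "character",
                 country_of_origin = "character",
                 country_of_recruitment = "character",
                 number_of_individuals = "integer", stage = "character"),
    pair = c(item_id = "integer", attribute = "character",
             value = "character"),
    kb_vocabulary = c(tid = "integer", ontology = "character",
                      ontology_id = "character", pref_label = "character",
                      description = "character", iri = "character"),
    kb_synonym = c(tid = "integer", label = "character"),
    kb_reference = c(tid = "integer", xref = "character"),
    kb_ontology = c(ontology = "character", acceptance = "numeric"),
    kb_relationship = c(parent_tid = "integer", child_tid = "integer",
                        kind = "character"))
}

empty_table <- function(spec) {
  out <- lapply(unname(spec), function(t) vector(t, 0L))
  names(out) <- names(spec)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read a declarative mapping-rules file
#'
#' A rules file is a TSV with columns `pattern` (anchored regular expression
#' over whole attribute names; rules targeting the Ancestry table carry one
#' capture group for the 1-based ordinal), `table`, `column` and `transform`
#' (`identity` or `integer`).
#'
#' @param path Path to the rules TSV.  The rules shipped for the two
#'   supported sources live under `system.file("extdata", package =
#'   "gdmgwas")` as `rules_gwas_catalog.tsv` and `rules_finngen.tsv`.
#' @return Validated `data.frame` of rules.
#' @export
read_mapping_rules <- function(path) {
  rules <- utils::read.delim(path, colClasses = "character",
                             comment.char = "#")
  validate_mapping_rules(rules)
}

validate_mapping_rules <- function(rules) {
  need <- c("pattern", "table", "column", "transform")
  if (!all(need %in% names(rules))) {
    stop("rules must have columns ", paste(need, collapse = ", "))
  }
  spec <- gcm_table_spec()
  for (i in seq_len(nrow(rules))) {
    tb <- rules$table[i]
    if (!tb %in% names(spec)) stop("rule targets unknown table: ", tb)
    if (!rules$column[i] %in% names(spec[[tb]])) {
      stop("rule targets unknown column: ", tb, ".", rules$column[i])
    }
    if (!rules$transform[i] %in% c("identity", "integer")) {
      stop("unknown transform: ", rules$transform[i])
    }
    if (tb == "ancestry" && !grepl("\\(", rules$pattern[i])) {
      stop("ancestry rule needs an ordinal capture group: ", rules$pattern[i])
    }
  }
  rules
}

#' Mapping rules shipped for a source
#' @param source `"gwas_catalog"` or `"finngen"`.
#' @return Rules `data.frame` as from [read_mapping_rules()].
#' @export
default_mapping_rules <- function(source = c("gwas_catalog", "finngen")) {
  source <- match.arg(source)
  read_mapping_rules(system.file("extdata", paste0("rules_", source, ".tsv"),
                                 package = "gdmgwas", mustWork = TRUE))
}

apply_transform <- function(value, transform, attribute) {
  if (transform == "integer") {
    v <- suppressWarnings(as.integer(value))
    if (is.na(v) && !is.na(value) && nzchar(value)) {
      warning("integer-cast failure for attribute '", attribute,
              "' value '", value, "': stored as missing", call. = FALSE)
    }
    v
  } else {
    value
  }
}

#' Map a GDM dataset into a GCM relational store
#'
#' Emits one Item and one Cohort per sample; one Ancestry row per distinct
#' ordinal captured by ancestry-pattern matches; CaseStudy rows deduplicated
#' by (pubmed_id, source_site); and every unmatched metadata attribute
#' preserved verbatim in the `pair` spillover table.
#'
#' @param dataset A [gdm_dataset()].
#' @param rules Mapping rules (see [read_mapping_rules()]).
#' @return Object of class `gcm_store`: a list of `data.frame`s
#'   (`item`, `case_study`, `cohort`, `ancestry`, `pair`, plus empty
#'   knowledge-base tables ready for enrichment).
#' @export
map_dataset <- function(dataset, rules) {
  rules <- validate_mapping_rules(rules)
  spec <- gcm_table_spec()
  store <- lapply(spec, empty_table)
  samples <- dataset$samples
  cs_key <- character()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    item <- list(item_id = i, sample_id = s$sample_id, source_id = NA_character_,
                 dataset_name = dataset$name, case_study_id = NA_integer_)
    case_study <- list(pubmed_id = NA_character_, source_site = dataset$name)
    cohort <- lapply(spec$cohort, function(t) as.vector(NA, mode = t))
    cohort$cohort_id <- i
    cohort$item_id <- i
    anc <- list()  # ordinal -> named list
    for (j in seq_len(nrow(s$metadata))) {
      attr_name <- s$metadata$attribute[j]
      val <- s$metadata$value[j]
      hits <- which(vapply(rules$pattern, function(p) {
        grepl(paste0("^", p, "$"), attr_name)
      }, logical(1)))
      if (length(hits) == 0L) {
        store$pair[nrow(store$pair) + 1L, ] <- list(i, attr_name, val)
        next
      }
      targets <- unique(paste0(rules$table[hits], ".", rules$column[hits]))
      if (length(targets) > 1L) {
        stop("rule conflict: attribute '", attr_name,
             "' matched by rules targeting ", paste(targets, collapse = " and "))
      }
      r <- hits[1L]
      v <- apply_transform(val, rules$transform[r], attr_name)
      tb <- rules$table[r]
      cl <- rules$column[r]
      if (tb == "item") {
        item[[cl]] <- v
      } else if (tb == "case_study") {
        case_study[[cl]] <- v
      } else if (tb == "cohort") {
        cohort[[cl]] <- v
      } else if (tb == "ancestry") {
        ord <- regmatches(attr_name,
                          regexec(paste0("^", rules$pattern[r], "$"), attr_name))[[1L]][2L]
        ord <- as.integer(ord)
        key <- as.character(ord)
        if (is.null(anc[[key]])) anc[[key]] <- list(ordinal = ord)
        anc[[key]][[cl]] <- v
      } else {
        stop("rules may not target table '", tb, "'")
      }
    }
    # CaseStudy: one row per distinct (pubmed_id, source_site)
    if (!is.na(case_study$pubmed_id)) {
      key <- paste(case_study$pubmed_id, case_study$source_site, sep = "\r")
      at <- match(key, cs_key)
      if (is.na(at)) {
        cs_key <- c(cs_key, key)
        at <- length(cs_key)
        store$case_study[at, ] <- list(at, case_study$pubmed_id,
                                       case_study$source_site)
      }
      item$case_study_id <- at
    }
    store$item[i, ] <- item[names(spec$item)]
    store$cohort[i, ] <- cohort[names(spec$cohort)]
    if (length(anc)) {
      ords <- sort(vapply(anc, function(a) a$ordinal, integer(1)))
      if (!identical(unname(ords), seq_along(ords))) {
        stop("ancestry ordinals for sample '", s$sample_id,
             "' are not contiguous from 1: ", paste(ords, collapse = ","))
      }
      for (ord in ords) {
        a <- anc[[as.character(ord)]]
        row <- lapply(spec$ancestry, function(t) as.vector(NA, mode = t))
        row$ancestry_id <- nrow(store$ancestry) + 1L
        row$cohort_id <- i
        for (nm in names(a)) row[[nm]] <- a[[nm]]
        store$ancestry[nrow(store$ancestry) + 1L, ] <- row[names(spec$ancestry)]
      }
    }
  }
  structure(store, class = "gcm_store")
}

#' @export
print.gcm_store <- function(x, ...) {
  cat("GCM relational store:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %d row(s)\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Check referential integrity and GWAS-view cardinality invariants
#'
#' @param store A `gcm_store`.
#' @return `TRUE` invisibly; stops with a descriptive error otherwise.
#' @export
check_store <- function(store) {
  if (anyDuplicated(store$item$source_id[!is.na(store$item$source_id)])) {
    stop("integrity: duplicate item source_id within dataset")
  }
  if (!identical(sort(store$cohort$item_id), sort(store$item$item_id))) {
    stop("integrity: cohorts are not 1:1 with items")
  }
  if (!all(store$ancestry$cohort_id %in% store$cohort$cohort_id)) {
    stop("integrity: ancestry row references missing cohort")
  }
  key <- paste(store$ancestry$cohort_id, store$ancestry$ordinal)
  if (anyDuplicated(key)) stop("integrity: duplicate (cohort, ordinal)")
  cs <- store$item$case_study_id
  if (!all(is.na(cs) | cs %in% store$case_study$case_study_id)) {
    stop("integrity: item references missing case study")
  }
  tid <- store$cohort$trait_name_tid
  if (!all(is.na(tid) | tid %in% store$kb_vocabulary$tid)) {
    stop("integrity: trait_name_tid references missing vocabulary term")
  }
  invisible(TRUE)
}

sql_type <- function(r_type) {
  switch(r_type, character = "TEXT", integer = "INTEGER", numeric = "REAL")
}

#' Export a GCM store as portable SQL DDL plus per-table TSV dumps
#'
#' @param store A `gcm_store`.
#' @param directory Output directory (created if needed).
#' @return `directory`, invisibly.  [load_store()] on the directory yields
#'   identical row multisets.
#' @export
export_store <- function(store, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  spec <- gcm_table_spec()
  ddl <- vapply(names(spec), function(tb) {
    cols <- spec[[tb]]
    defs <- paste0("  ", names(cols), " ", vapply(unname(cols), sql_type,
                                                  character(1)))
    pk <- names(cols)[1L]
    if (endsWith(pk, "_id") || pk == "tid") {
      defs[1L] <- paste0(defs[1L], " PRIMARY KEY")
    }
    paste0("CREATE TABLE ", tb, " (\n", paste(defs, collapse = ",\n"), "\n);")
  }, character(1))
  writeLines(ddl, file.path(directory, "gcm_schema.sql"))
  for (tb in names(spec)) {
    utils::write.table(store[[tb]], file.path(directory, paste0(tb, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }
  invisible(directory)
}

#' Reload a GCM store exported by [export_store()]
#'
#' @param directory Directory written by [export_store()].
#' @return A `gcm_store`.
#' @export
load_store <- function(directory) {
  spec <- gcm_table_spec()
  store <- lapply(names(spec), function(tb) {
    path <- file.path(directory, paste0(tb, ".tsv"))
    if (!file.exists(path)) stop("missing table dump: ", path)
    df <- utils::read.delim(path, colClasses = unname(spec[[tb]]),
                            check.names = FALSE, quote = "",
                            na.strings = "NA")
    names(df) <- names(spec[[tb]])
    df
  })
  names(store) <- names(spec)
  structure(store, class = "gcm_store")
}
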