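#' Local knowledge base and ontology term sources
#'
#' The knowledge base caches every ontology term used for annotation --
#' vocabulary (one row per term, keyed by a surrogate `tid`), synonyms,
#' cross-references, per-ontology details, and is_a/part_of relationships
#' between terms reachable within a configurable number of ontology levels
#' from each base term (default 3, both upwards and downwards).
#'
#' Term lookups go through a *term source* interface; the offline backend
#' bundled here serves term records from a JSON corpus in the shape of
#' ontology-lookup responses (id, preferred label, synonyms, xrefs,
#' parent/child links with relation kind).
#'
#' @name knowledge_base
NULL

#' Create an empty knowledge base
#' @return Object of class `knowledge_base` with empty `vocabulary`,
#'   `synonym`, `reference`, `ontology` and `relationship` tables.
#' @export
new_knowledge_base <- function() {
  spec <- gcm_table_spec()
  kb <- list(vocabulary = empty_table(spec$kb_vocabulary),
             synonym = empty_table(spec$kb_synonym),
             reference = empty_table(spec$kb_reference),
             ontology = empty_table(spec$kb_ontology),
             relationship = empty_table(spec$kb_relationship))
  structure(kb, class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("Knowledge base:", nrow(x$vocabulary), "terms,",
      nrow(x$synonym), "synonyms,", nrow(x$relationship), "relationships\n")
  invisible(x)
}

kb_tid <- function(kb, ontology, ontology_id) {
  hit <- which(kb$vocabulary$ontology == ontology &
                 kb$vocabulary$ontology_id == ontology_id)
  if (length(hit)) kb$vocabulary$tid[hit[1L]] else NA_integer_
}

kb_insert_term <- function(kb, term) {
  tid <- kb_tid(kb, term$ontology, term$ontology_id)
  if (!is.na(tid)) return(list(kb = kb, tid = tid))
  tid <- nrow(kb$vocabulary) + 1L
  kb$vocabulary[tid, ] <- list(tid, term$ontology, term$ontology_id,
                               term$pref_label,
                               if (is.null(term$description)) NA_character_
                               else term$description,
                               if (is.null(term$iri)) NA_character_
                               else term$iri)
  for (s in term$synonyms) {
    kb$synonym[nrow(kb$synonym) + 1L, ] <- list(tid, s)
  }
  for (x in term$xrefs) {
    kb$reference[nrow(kb$reference) + 1L, ] <- list(tid, x)
  }
  if (!term$ontology %in% kb$ontology$ontology) {
    kb$ontology[nrow(kb$ontology) + 1L, ] <- list(term$ontology, NA_real_)
  }
  list(kb = kb, tid = tid)
}

kb_add_relationship <- function(kb, parent_tid, child_tid, kind) {
  dup <- any(kb$relationship$parent_tid == parent_tid &
               kb$relationship$child_tid == child_tid &
               kb$relationship$kind == kind)
  if (!dup) {
    kb$relationship[nrow(kb$relationship) + 1L, ] <-
      list(parent_tid, child_tid, kind)
  }
  kb
}

#' Insert a term and its ontological neighbourhood into the knowledge base
#'
#' Inserts the term's vocabulary, synonym and reference rows, then traverses
#' its hyperonyms (ancestors) and hyponyms (descendants) up to `levels`
#' ontology levels, inserting each related term and a relationship row
#' carrying the relation kind (`is_a` or `part_of`).  Re-insertion of an
#' existing term is a no-op; a related term missing from the term source is
#' skipped with a warning.
#'
#' @param kb A [new_knowledge_base()].
#' @param term A [term_record()].
#' @param term_source A term source (see [term_source_fixture()]).
#' @param levels Traversal depth, `>= 0` (default 3).
#' @return The updated `knowledge_base`, with the base term's `tid` in
#'   attribute `"tid"`.
#' @export
populate_kb <- function(kb, term, term_source, levels = 3L) {
  stopifnot(levels >= 0L)
  ins <- kb_insert_term(kb, term)
  kb <- ins$kb
  base_tid <- ins$tid
  for (direction in c("parents", "children")) {
    frontier <- list(list(term = term, tid = base_tid))
    for (lvl in seq_len(levels)) {
      nxt <- list()
      for (node in frontier) {
        for (link in node$term[[direction]]) {
          rel <- ts_get(term_source, link$ontology, link$ontology_id)
          if (is.null(rel)) {
            warning("dangling ", substr(direction, 1, nchar(direction) - 1L),
                    " reference ", link$ontology, ":", link$ontology_id,
                    " skipped", call. = FALSE)
            next
          }
          ins <- kb_insert_term(kb, rel)
          kb <- ins$kb
          kind <- if (is.null(link$kind)) "is_a" else link$kind
          if (direction == "parents") {
            kb <- kb_add_relationship(kb, ins$tid, node$tid, kind)
          } else {
            kb <- kb_add_relationship(kb, node$tid, ins$tid, kind)
          }
          nxt[[length(nxt) + 1L]] <- list(term = rel, tid = ins$tid)
        }
      }
      if (!length(nxt)) break
      frontier <- nxt
    }
  }
  attr(kb, "tid") <- base_tid
  kb
}

#' Offline term source backed by an in-memory corpus
#'
#' @param terms List of [term_record()]s (duplicate (ontology, id) pairs are
#'   an error).
#' @return Object of class `term_source_fixture`.
#' @export
term_source_fixture <- function(terms) {
  keys <- vapply(terms, function(t) paste(t$ontology, t$ontology_id, sep = ":"),
                 character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate term id(s) in corpus: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  names(terms) <- keys
  structure(list(terms = terms), class = c("term_source_fixture", "term_source"))
}

#' Fetch one term record from a term source
#' @param source A term source.
#' @param ontology,ontology_id Term key.
#' @return A [term_record()], or `NULL` if absent.
#' @export
ts_get <- function(source, ontology, ontology_id) {
  UseMethod("ts_get")
}

#' @export
ts_get.term_source_fixture <- function(source, ontology, ontology_id) {
  source$terms[[paste(ontology, ontology_id, sep = ":")]]
}

#' List the terms a term source holds for given ontologies
#' @param source A term source.
#' @param ontologies Character vector of ontology names, or `NULL` for all.
#' @return List of [term_record()]s.
#' @export
ts_terms <- function(source, ontologies = NULL) {
  UseMethod("ts_terms")
}

#' @export
ts_terms.term_source_fixture <- function(source, ontologies = NULL) {
  terms <- source$terms
  if (!is.null(ontologies)) {
    keep <- vapply(terms, function(t) t$ontology %in% ontologies, logical(1))
    terms <- terms[keep]
  }
  unname(terms)
}

term_to_list <- function(t) {
  list(ontology = t$ontology, ontology_id = t$ontology_id,
       pref_label = t$pref_label, synonyms = as.list(t$synonyms),
       description = t$description, iri = t$iri, xrefs = as.list(t$xrefs),
       parents = t$parents, children = t$children)
}

list_to_term <- function(l) {
  fix_links <- function(lk) {
    lapply(lk, function(x) list(ontology = x$ontology,
                                ontology_id = x$ontology_id,
                                kind = if (is.null(x$kind)) "is_a" else x$kind))
  }
  term_record(l$ontology, l$ontology_id, l$pref_label,
              synonyms = unlist(l$synonyms, use.names = FALSE),
              description = if (is.null(l$description)) NA_character_
              else l$description,
              iri = if (is.null(l$iri)) NA_character_ else l$iri,
              xrefs = if (length(l$xrefs)) unlist(l$xrefs, use.names = FALSE)
              else character(),
              parents = fix_links(l$parents), children = fix_links(l$children))
}

#' Write / read a JSON term corpus
#'
#' @param terms List of [term_record()]s.
#' @param path JSON file path.
#' @return `write_term_corpus()` returns `path` invisibly;
#'   `read_term_corpus()` returns a [term_source_fixture()].
#' @export
write_term_corpus <- function(terms, path) {
  term_source_fixture(terms)  # validates uniqueness
  jsonlite::write_json(lapply(terms, term_to_list), path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_term_corpus
#' @export
read_term_corpus <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  term_source_fixture(lapply(raw, list_to_term))
}

#' Search a term source for candidate annotations of one parsed value
#'
#' Brute-force scoring of every term of the requested ontologies against the
#' parsed value (the offline analogue of a keyword lookup against an
#' ontology search service).
#'
#' @param source A term source.
#' @param parsed A `parsed_value` or character scalar.
#' @param ontologies Ontologies to search, `NULL` for all.
#' @param min_score Discard candidates below this match score (default 0).
#' @return `data.frame` of candidates (see [match_score()]), unranked.
#' @export
search_terms <- function(source, parsed, ontologies = NULL, min_score = 0) {
  parsed <- as_parsed_value(parsed)
  cands <- lapply(ts_terms(source, ontologies), function(t) {
    match_score(parsed, t)
  })
  df <- candidates_to_df(cands)
  df[df$match_score >= min_score, , drop = FALSE]
}
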