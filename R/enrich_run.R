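#' Running the enrichment over a mapped store
#'
#' For every trait value the procedure first looks for a suitable term
#' already in the knowledge base; only if none is found is a match searched
#' on the configured ontologies through the term source.  Values whose best
#' annotation reaches a match score of at least `min_match` (default 5, out
#' of 10 for a perfect preferred-label match) are auto-linked by setting
#' `trait_name_tid`; the rest are queued for manual curation together with
#' ranked suggestions.  Original trait values are never modified.
#'
#' @name enrich_pipeline
NULL

norm_label <- function(x) {
  vapply(x, function(s) paste(tokenize_label(s), collapse = " "), character(1),
         USE.NAMES = FALSE)
}

kb_lookup_value <- function(kb, parsed) {
  hit <- which(norm_label(kb$vocabulary$pref_label) == parsed$parsed)
  if (length(hit)) return(kb$vocabulary$tid[hit[1L]])
  hit <- which(norm_label(kb$synonym$label) == parsed$parsed)
  if (length(hit)) return(kb$synonym$tid[hit[1L]])
  NA_integer_
}

#' Enrich the trait names of a mapped store with ontology terms
#'
#' @param store A `gcm_store` from [map_dataset()].
#' @param kb A [new_knowledge_base()] (possibly already holding terms from
#'   earlier runs; sharing one knowledge base across sources makes their
#'   term ids comparable, see [common_concepts()]).
#' @param ontologies Character vector of ontologies to search, in no
#'   particular order (e.g. `c("EFO", "NCIT")`).
#' @param term_source Term source to query, e.g. [term_source_fixture()].
#' @param acceptance Named per-ontology acceptance map covering
#'   `ontologies`.
#' @param min_match Auto-accept threshold on the match score (default 5).
#' @param weights Annotation-score weights, default
#'   [default_annotation_weights()].
#' @param kb_depth Relationship traversal depth for [populate_kb()].
#' @return List of class `enrichment` with elements `store` (the store with
#'   `trait_name_tid` filled and knowledge-base tables attached), `kb`, and
#'   `queue` (curation queue: one row per unlinked value with ranked
#'   suggestions).  Rerunning on the returned store changes nothing.
#' @export
enrich <- function(store, kb, ontologies, term_source, acceptance,
                   min_match = 5, weights = NULL, kb_depth = 3L) {
  if (is.null(weights)) weights <- default_annotation_weights()
  missing_acc <- setdiff(ontologies, names(acceptance))
  if (length(missing_acc)) {
    stop("no acceptance score for: ", paste(missing_acc, collapse = ", "))
  }
  todo <- !is.na(store$cohort$trait_name) & nzchar(store$cohort$trait_name) &
    is.na(store$cohort$trait_name_tid)
  raw_values <- unique(store$cohort$trait_name[todo])
  linked <- stats::setNames(rep(NA_integer_, length(raw_values)), raw_values)
  queue <- data.frame(trait_name = character(), parsed = character(),
                      suggestions = character(), stringsAsFactors = FALSE)

  parsed_by_raw <- lapply(raw_values, function(r) {
    tryCatch(parse_raw_value(r), warning = function(w) list())
  })
  names(parsed_by_raw) <- raw_values

  # knowledge-base lookups complete the procedure without a search
  need_search <- character()
  for (r in raw_values) {
    tid <- NA_integer_
    for (pv in parsed_by_raw[[r]]) {
      tid <- kb_lookup_value(kb, pv)
      if (!is.na(tid)) break
    }
    if (!is.na(tid)) linked[r] <- tid else need_search <- c(need_search, r)
  }

  # search the configured ontologies for what the KB does not know
  if (length(need_search)) {
    cand_list <- list()
    for (r in need_search) {
      for (pv in parsed_by_raw[[r]]) {
        df <- search_terms(term_source, pv, ontologies)
        if (nrow(df)) cand_list[[length(cand_list) + 1L]] <- df
      }
    }
    cands <- if (length(cand_list)) do.call(rbind, cand_list) else
      candidates_to_df(list())
    if (nrow(cands)) {
      # best candidate per (raw value, ontology, term)
      cands <- cands[order(cands$raw, cands$ontology, cands$ontology_id,
                           -cands$match_score, cands$basis), , drop = FALSE]
      cands <- cands[!duplicated(cands[, c("raw", "ontology", "ontology_id")]), ,
                     drop = FALSE]
      per_value_onto <- cands[order(cands$raw, cands$ontology,
                                    -cands$match_score), , drop = FALSE]
      per_value_onto <- per_value_onto[!duplicated(
        per_value_onto[, c("raw", "ontology")]), , drop = FALSE]
      scores <- ontology_scores(per_value_onto, length(need_search), acceptance)
      cands$suitability <- scores$suitability[match(cands$ontology,
                                                    scores$ontology)]
      cands$acceptance <- unname(acceptance[cands$ontology])
      cands$annotation_score <- annotation_score(
        cands$match_score, cands$suitability, cands$acceptance, weights)
      cands <- cands[order(cands$raw, -cands$annotation_score, cands$basis,
                           cands$ontology, cands$ontology_id), , drop = FALSE]
    }
    for (r in need_search) {
      sub <- cands[cands$raw == r, , drop = FALSE]
      if (nrow(sub) && sub$match_score[1L] >= min_match) {
        term <- ts_get(term_source, sub$ontology[1L], sub$ontology_id[1L])
        kb <- populate_kb(kb, term, term_source, kb_depth)
        linked[r] <- attr(kb, "tid")
      } else {
        sugg <- if (nrow(sub)) {
          top <- utils::head(sub, 3L)
          paste(sprintf("%s:%s match=%.1f ann=%.2f", top$ontology,
                        top$ontology_id, top$match_score,
                        top$annotation_score), collapse = "; ")
        } else {
          ""
        }
        queue[nrow(queue) + 1L, ] <- list(
          r, paste(vapply(parsed_by_raw[[r]], `[[`, character(1), "parsed"),
                   collapse = " | "), sugg)
      }
    }
  }

  store$cohort$trait_name_tid[todo] <-
    unname(linked[store$cohort$trait_name[todo]])
  for (o in ontologies) {
    at <- match(o, kb$ontology$ontology)
    if (is.na(at)) {
      kb$ontology[nrow(kb$ontology) + 1L, ] <- list(o, unname(acceptance[o]))
    } else {
      kb$ontology$acceptance[at] <- unname(acceptance[o])
    }
  }
  store$kb_vocabulary <- kb$vocabulary
  store$kb_synonym <- kb$synonym
  store$kb_reference <- kb$reference
  store$kb_ontology <- kb$ontology
  store$kb_relationship <- kb$relationship
  structure(list(store = store, kb = kb, queue = queue), class = "enrichment")
}

#' @export
print.enrichment <- function(x, ...) {
  n_linked <- sum(!is.na(x$store$cohort$trait_name_tid))
  cat("Enrichment:", n_linked, "of", nrow(x$store$cohort),
      "cohort trait values linked;", nrow(x$queue), "queued for curation\n")
  invisible(x)
}

store_annotation_refs <- function(store) {
  coh <- store$cohort[!is.na(store$cohort$trait_name_tid), , drop = FALSE]
  data.frame(tid = coh$trait_name_tid,
             sample_id = store$item$sample_id[match(coh$item_id,
                                                    store$item$item_id)],
             stringsAsFactors = FALSE)
}

#' Ontology concepts shared across enriched data sources
#'
#' A common concept is an ontological term referenced (via
#' `trait_name_tid`) by at least one dataset of every source.  Meaningful
#' when the sources were enriched against a shared knowledge base, so term
#' ids are comparable.
#'
#' @param by_source Named list (one element per source) of enriched
#'   `gcm_store`s, or of `data.frame`s with columns `tid`, `sample_id`.
#' @param kb Optional [new_knowledge_base()] used to label the output.
#' @return `data.frame` with one row per common term: `tid`, plus (if `kb`
#'   is given) `ontology`, `ontology_id`, `pref_label`, plus one
#'   comma-joined sample-id column per source.
#' @export
common_concepts <- function(by_source, kb = NULL) {
  stopifnot(length(by_source) >= 2L, !is.null(names(by_source)))
  refs <- lapply(by_source, function(x) {
    if (inherits(x, "gcm_store")) store_annotation_refs(x) else x
  })
  shared <- Reduce(intersect, lapply(refs, function(r) unique(r$tid)))
  shared <- sort(shared)
  out <- data.frame(tid = shared)
  if (!is.null(kb)) {
    at <- match(shared, kb$vocabulary$tid)
    out$ontology <- kb$vocabulary$ontology[at]
    out$ontology_id <- kb$vocabulary$ontology_id[at]
    out$pref_label <- kb$vocabulary$pref_label[at]
  }
  for (src in names(refs)) {
    out[[paste0("samples_", src)]] <- vapply(shared, function(t) {
      paste(sort(unique(refs[[src]]$sample_id[refs[[src]]$tid == t])),
            collapse = ",")
    }, character(1))
  }
  out
}
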