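#' Flattening integrated metadata back to GDM files
#'
#' After mapping (and optionally enrichment) the relational metadata is fed
#' back to the file-based GDM representation, so file-oriented pipelines see
#' the integration results.  Region files are copied byte-identically; only
#' metadata files gain pairs.
#'
#' @name flattener
NULL

pair_or_empty <- function(keys, values) {
  keep <- !is.na(values) & nzchar(as.character(values))
  data.frame(attribute = keys[keep], value = as.character(values)[keep],
             stringsAsFactors = FALSE)
}

#' Flatten a mapped (and possibly enriched) store over a GDM dataset
#'
#' Each sample's output metadata file holds, in deterministic order: the
#' original pairs; the mapped global-schema pairs under dotted
#' `table.column` keys (ancestry columns with their `_<ordinal>` suffix);
#' and, when the trait was enriched, the annotation pairs
#' `cohort.trait_name_tid`, `cohort.trait_name_ontology`,
#' `cohort.trait_name_ontology_id`, `cohort.trait_name_pref_label`.
#' Dotted keys cannot collide with source attribute names, which are
#' snake-case only.
#'
#' @param store A `gcm_store` whose items reference samples of `dataset`.
#' @param dataset The [gdm_dataset()] the store was mapped from.
#' @param out_dir Output directory.
#' @return `out_dir` invisibly.  Running twice yields byte-identical files.
#' @export
flatten <- function(store, dataset, out_dir) {
  missing <- setdiff(store$item$sample_id, names(dataset$samples))
  if (length(missing)) {
    stop("store items reference sample(s) missing from dataset: ",
         paste(missing, collapse = ", "))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_gdm_schema(dataset$schema,
                   file.path(out_dir, paste0(dataset$name, ".schema.xml")))
  for (i in seq_len(nrow(store$item))) {
    sample <- dataset$samples[[store$item$sample_id[i]]]
    item_id <- store$item$item_id[i]
    mapped <- pair_or_empty(c("item.source_id", "item.dataset_name"),
                            c(store$item$source_id[i],
                              store$item$dataset_name[i]))
    cs_id <- store$item$case_study_id[i]
    if (!is.na(cs_id)) {
      at <- match(cs_id, store$case_study$case_study_id)
      mapped <- rbind(mapped, pair_or_empty(
        c("case_study.pubmed_id", "case_study.source_site"),
        c(store$case_study$pubmed_id[at], store$case_study$source_site[at])))
    }
    coh_at <- match(item_id, store$cohort$item_id)
    coh <- store$cohort[coh_at, , drop = FALSE]
    coh_cols <- setdiff(names(coh), c("cohort_id", "item_id", "trait_name_tid"))
    mapped <- rbind(mapped, pair_or_empty(paste0("cohort.", coh_cols),
                                          unlist(coh[1L, coh_cols])))
    anc <- store$ancestry[store$ancestry$cohort_id == coh$cohort_id, ,
                          drop = FALSE]
    anc <- anc[order(anc$ordinal), , drop = FALSE]
    for (k in seq_len(nrow(anc))) {
      a_cols <- setdiff(names(anc), c("ancestry_id", "cohort_id", "ordinal"))
      mapped <- rbind(mapped, pair_or_empty(
        paste0("ancestry.", a_cols, "_", anc$ordinal[k]),
        unlist(anc[k, a_cols])))
    }
    enrichment <- NULL
    tid <- coh$trait_name_tid
    if (!is.na(tid) && nrow(store$kb_vocabulary)) {
      v <- match(tid, store$kb_vocabulary$tid)
      enrichment <- pair_or_empty(
        c("cohort.trait_name_tid", "cohort.trait_name_ontology",
          "cohort.trait_name_ontology_id", "cohort.trait_name_pref_label"),
        c(tid, store$kb_vocabulary$ontology[v],
          store$kb_vocabulary$ontology_id[v],
          store$kb_vocabulary$pref_label[v]))
    }
    mapped <- mapped[order(mapped$attribute), , drop = FALSE]
    out_meta <- rbind(sample$metadata, mapped, enrichment)
    out_sample <- gdm_sample(sample$sample_id, sample$regions, out_meta,
                             dataset$schema)
    write_gdm_sample(out_sample, dataset$schema, out_dir)
  }
  invisible(out_dir)
}
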