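#' Transformation of ingested source rows into GDM datasets
#'
#' Both sources represent SNPs, so every emitted region is a 1-bp interval:
#' `stop = start + 1` and strand `'*'` (strand is not reported by either
#' source).  Chromosome tokens are normalized to `chr`-prefixed form
#' (`"13"` becomes `"chr13"`); already-prefixed values pass through.
#'
#' @name transformer
NULL

normalize_chrom <- function(x) {
  x <- trimws(x)
  ifelse(grepl("^chr", x, ignore.case = TRUE),
         paste0("chr", sub("^chr", "", x, ignore.case = TRUE)),
         paste0("chr", x))
}

#' Region schema for GWAS Catalog associations
#' @return A [region_schema()] whose variable part carries the association
#'   attributes copied verbatim from the `Associations` file.
#' @export
catalog_region_schema <- function() {
  region_schema("gwas_catalog", data.frame(
    name = c("strongest_snp_risk_allele", "reported_genes", "p_value"),
    type = c("text", "text", "float"),
    stringsAsFactors = FALSE))
}

#' Region schema for FinnGen summary statistics
#' @return A [region_schema()] whose variable part carries the per-variant
#'   columns copied as is from the summary-statistics files.
#' @export
finngen_region_schema <- function() {
  region_schema("finngen", data.frame(
    name = c("ref", "alt", "rsid", "pval"),
    type = c("text", "text", "text", "float"),
    stringsAsFactors = FALSE))
}

#' Resolve genomic coordinates of GWAS Catalog association rows
#'
#' Coordinates come from `CHR_ID`/`CHR_POS` when present; otherwise a
#' `chr<N>:<pos>`-shaped token before the first `-` of
#' `STRONGEST SNP-RISK ALLELE` is parsed.  Rows yielding neither are
#' unresolved (a value, not an error).  `stop` is `start + 1` and strand
#' is `'*'`.
#'
#' @param associations `data.frame` as returned in `read_catalog()$associations`
#'   (columns `chr_id`, `chr_pos`, `strongest_snp_risk_allele`).
#' @return `data.frame` with columns `chrom`, `start`, `stop`, `strand`,
#'   `resolved` (logical), one row per input row.
#' @export
resolve_catalog_coordinates <- function(associations) {
  n <- nrow(associations)
  chrom <- rep(NA_character_, n)
  start <- rep(NA_integer_, n)
  has_direct <- !is.na(associations$chr_pos) &
    !is.na(associations$chr_id) & nzchar(trimws(associations$chr_id))
  chrom[has_direct] <- normalize_chrom(associations$chr_id[has_direct])
  start[has_direct] <- associations$chr_pos[has_direct]
  # fallback: parse `chr?<chrom>:<integer>` before the first '-'
  need <- !has_direct
  if (any(need)) {
    token <- sub("-.*$", "", trimws(associations$strongest_snp_risk_allele[need]))
    m <- regmatches(token, regexec("^(?:chr)?([0-9XYMT]+):([0-9]+)$", token,
                                   ignore.case = TRUE))
    ok <- lengths(m) == 3L
    chrom[need][ok] <- normalize_chrom(vapply(m[ok], `[`, character(1), 2L))
    start[need][ok] <- as.integer(vapply(m[ok], `[`, character(1), 3L))
  }
  resolved <- !is.na(chrom) & !is.na(start)
  data.frame(chrom = chrom, start = start, stop = start + 1L,
             strand = ifelse(resolved, "*", NA_character_),
             resolved = resolved, stringsAsFactors = FALSE)
}

to_snake <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

add_pair <- function(meta, attribute, value) {
  value <- as.character(value)
  keep <- !is.na(value) & nzchar(trimws(value))
  if (!any(keep)) return(meta)
  rbind(meta, data.frame(attribute = attribute[keep], value = value[keep],
                         stringsAsFactors = FALSE))
}

#' Transform GWAS Catalog rows into a GDM dataset
#'
#' One sample per `Studies` row (i.e. per study-trait entry, matching the
#' Catalog's per-trait splitting); its regions are the resolvable
#' associations sharing the study accession, with the remaining association
#' attributes copied verbatim.  Metadata pairs are assembled from the
#' `Studies` columns plus the `Ancestry` rows of the accession, the latter
#' with 1-based ordinal suffixes `_1.._n` in file order
#' (`broad_ancestral_category_1`, ...).
#'
#' A multi-trait accession contributes its full region set to each of its
#' trait samples (replication is reported via a message).  Studies with zero
#' resolvable associations yield a 0-region sample and a warning.
#'
#' @param catalog List as returned by [read_catalog()], or the three
#'   `data.frame`s passed via `studies`, `ancestries`, `associations`.
#' @param studies,ancestries,associations Overrides for the components of
#'   `catalog`.
#' @param dataset_name Name of the emitted dataset.
#' @return A [gdm_dataset()] under [catalog_region_schema()].
#' @export
transform_catalog <- function(catalog = NULL, studies = catalog$studies,
                              ancestries = catalog$ancestries,
                              associations = catalog$associations,
                              dataset_name = "gwas_catalog") {
  schema <- catalog_region_schema()
  coords <- resolve_catalog_coordinates(associations)
  n_unres <- sum(!coords$resolved)
  if (n_unres) {
    message(n_unres, " association row(s) without resolvable coordinates ",
            "left out of region files")
  }
  acc <- studies$study_accession
  dup_acc <- duplicated(acc) | duplicated(acc, fromLast = TRUE)
  if (any(duplicated(acc))) {
    message("multi-trait accession(s) ",
            paste(unique(acc[duplicated(acc)]), collapse = ", "),
            ": region sets replicated across their trait samples")
  }
  # sample ids stay unique when one accession spans several trait entries
  ids <- acc
  for (a in unique(acc[duplicated(acc)])) {
    idx <- which(acc == a)
    ids[idx] <- paste0(a, "_", seq_along(idx))
  }
  extra_cols <- setdiff(names(studies),
                        c("study_accession", "disease_trait", "pubmed_id"))
  samples <- vector("list", nrow(studies))
  for (i in seq_len(nrow(studies))) {
    sel <- associations$study_accession == acc[i] & coords$resolved
    regions <- data.frame(
      chrom = coords$chrom[sel], start = coords$start[sel],
      stop = coords$stop[sel], strand = coords$strand[sel],
      strongest_snp_risk_allele = associations$strongest_snp_risk_allele[sel],
      reported_genes = associations$reported_genes[sel],
      p_value = associations$p_value[sel],
      stringsAsFactors = FALSE)
    if (nrow(regions) == 0L) {
      warning("study entry '", ids[i], "' has no resolvable associations; ",
              "emitting a 0-region sample", call. = FALSE)
      regions <- empty_regions(schema)
    }
    meta <- data.frame(attribute = character(), value = character(),
                       stringsAsFactors = FALSE)
    meta <- add_pair(meta, "study_accession", acc[i])
    meta <- add_pair(meta, "disease_trait", studies$disease_trait[i])
    meta <- add_pair(meta, "pubmed_id", studies$pubmed_id[i])
    for (cn in extra_cols) meta <- add_pair(meta, to_snake(cn), studies[[cn]][i])
    arows <- which(ancestries$study_accession == acc[i])
    for (k in seq_along(arows)) {
      r <- arows[k]
      meta <- add_pair(meta,
                       paste0(c("stage_", "broad_ancestral_category_",
                                "country_of_origin_", "country_of_recruitment_",
                                "number_of_individuals_"), k),
                       c(ancestries$stage[r],
                         ancestries$broad_ancestral_category[r],
                         ancestries$country_of_origin[r],
                         ancestries$country_of_recruitment[r],
                         ancestries$number_of_individuals[r]))
    }
    samples[[i]] <- gdm_sample(ids[i], regions, meta, schema)
  }
  gdm_dataset(dataset_name, schema, samples)
}

#' Transform FinnGen endpoints into a GDM dataset
#'
#' One sample per endpoint; one region per variant row with coordinates
#' (`chrom` from `#chrom`, `start = pos`, `stop = pos + 1`, strand `'*'`)
#' and the remaining columns copied as variable attributes.  Metadata holds
#' the endpoint name and trait label.  Variants with nonpositive positions
#' are skipped with a warning.
#'
#' @param entries List as returned by [read_finngen()].
#' @param dataset_name Name of the emitted dataset.
#' @return A [gdm_dataset()] under [finngen_region_schema()].
#' @export
transform_finngen <- function(entries, dataset_name = "finngen") {
  schema <- finngen_region_schema()
  samples <- lapply(entries, function(e) {
    v <- e$variants
    bad <- is.na(v$pos) | v$pos <= 0L
    if (any(bad)) {
      warning(sum(bad), " variant(s) with nonpositive position skipped in ",
              "endpoint '", e$endpoint$endpoint_name, "'", call. = FALSE)
      v <- v[!bad, , drop = FALSE]
    }
    regions <- if (nrow(v)) {
      data.frame(chrom = normalize_chrom(v$chrom), start = v$pos,
                 stop = v$pos + 1L, strand = "*",
                 ref = v$ref, alt = v$alt, rsid = v$rsid, pval = v$pval,
                 stringsAsFactors = FALSE)
    } else {
      empty_regions(schema)
    }
    meta <- data.frame(attribute = character(), value = character(),
                       stringsAsFactors = FALSE)
    meta <- add_pair(meta, "endpoint_name", e$endpoint$endpoint_name)
    meta <- add_pair(meta, "trait_name", e$endpoint$trait_label)
    meta <- add_pair(meta, "source", "finngen")
    gdm_sample(e$endpoint$endpoint_name, regions, meta, schema)
  })
  gdm_dataset(dataset_name, schema, samples)
}
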