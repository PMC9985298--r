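#' Readers for GWAS Catalog dumps and FinnGen releases
#'
#' The GWAS Catalog distributes summary-level results as three tab-separated
#' files -- `Studies` (one row per study-trait entry; multi-trait studies are
#' split across rows), `Ancestry` (cohort partitions with size and
#' geographical provenance) and `Associations` (one row per SNP-trait
#' association) -- joinable on `STUDY ACCESSION`.  FinnGen publishes a
#' manifest of endpoints (its term for traits) pointing to per-endpoint
#' summary-statistics TSVs whose coordinate columns are `#chrom` and `pos`.
#'
#' Header matching is case-insensitive and ignores surrounding whitespace;
#' columns beyond the mandatory downstream set ride along untouched.
#'
#' @name source_ingest
NULL

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, colClasses = "character", check.names = FALSE,
                    quote = "", comment.char = "", na.strings = NULL,
                    blank.lines.skip = TRUE)
}

norm_header <- function(x) toupper(trimws(x))

find_col <- function(df, header, path, required = TRUE) {
  idx <- which(norm_header(names(df)) == norm_header(header))
  if (length(idx) == 0L) {
    if (required) stop("format error: required column '", header,
                       "' missing from ", path)
    return(NULL)
  }
  trimws(df[[idx[1L]]])
}

parse_int_col <- function(x, what, path) {
  v <- suppressWarnings(as.integer(x))
  bad <- !is.na(x) & nzchar(x) & is.na(v)
  if (any(bad)) {
    warning(sum(bad), " unparseable ", what, " value(s) in ", basename(path),
            " set to missing (e.g. '", x[which(bad)[1L]], "')", call. = FALSE)
  }
  v
}

parse_num_col <- function(x, what, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & nzchar(x) & is.na(v)
  if (any(bad)) {
    warning(sum(bad), " unparseable ", what, " value(s) in ", basename(path),
            " set to missing", call. = FALSE)
  }
  v
}

extras_of <- function(df, used_headers) {
  keep <- !(norm_header(names(df)) %in% norm_header(used_headers))
  df[, keep, drop = FALSE]
}

#' Read a GWAS Catalog three-file dump
#'
#' @param studies_path,ancestry_path,associations_path Paths to the
#'   tab-separated `Studies`, `Ancestry` and `Associations` files (with
#'   header rows).
#' @return List with typed `data.frame`s `studies`, `ancestries`,
#'   `associations`.  Canonical columns come first; unrecognized source
#'   columns are preserved verbatim after them.  Unparseable numeric cells
#'   raise a warning and become `NA`; the row is retained.
#' @export
read_catalog <- function(studies_path, ancestry_path, associations_path) {
  sdf <- read_tsv_raw(studies_path)
  studies <- data.frame(
    study_accession = find_col(sdf, "STUDY ACCESSION", studies_path),
    disease_trait = find_col(sdf, "DISEASE/TRAIT", studies_path),
    pubmed_id = find_col(sdf, "PUBMEDID", studies_path),
    stringsAsFactors = FALSE)
  if (any(!nzchar(studies$study_accession))) {
    stop("format error: empty STUDY ACCESSION in ", studies_path)
  }
  studies <- cbind(studies, extras_of(
    sdf, c("STUDY ACCESSION", "DISEASE/TRAIT", "PUBMEDID")))

  adf <- read_tsv_raw(ancestry_path)
  stage_raw <- tolower(find_col(adf, "STAGE", ancestry_path))
  if (nrow(adf) && !all(stage_raw %in% c("initial", "replication"))) {
    stop("format error: unrecognized STAGE value(s) in ", ancestry_path, ": ",
         paste(unique(setdiff(stage_raw, c("initial", "replication"))),
               collapse = ", "))
  }
  n_ind <- parse_int_col(find_col(adf, "NUMBER OF INDIVIDUALS", ancestry_path),
                         "NUMBER OF INDIVIDUALS", ancestry_path)
  if (any(!is.na(n_ind) & n_ind < 0L)) {
    stop("format error: negative NUMBER OF INDIVIDUALS in ", ancestry_path)
  }
  ancestries <- data.frame(
    study_accession = find_col(adf, "STUDY ACCESSION", ancestry_path),
    stage = stage_raw,
    number_of_individuals = n_ind,
    broad_ancestral_category = find_col(adf, "BROAD ANCESTRAL CATEGORY",
                                        ancestry_path),
    country_of_origin = find_col(adf, "COUNTRY OF ORIGIN", ancestry_path),
    country_of_recruitment = find_col(adf, "COUNTRY OF RECRUITMENT",
                                      ancestry_path),
    stringsAsFactors = FALSE)

  xdf <- read_tsv_raw(associations_path)
  p_value <- parse_num_col(find_col(xdf, "P-VALUE", associations_path),
                           "P-VALUE", associations_path)
  if (any(!is.na(p_value) & p_value < 0)) {
    stop("format error: negative P-VALUE in ", associations_path)
  }
  associations <- data.frame(
    study_accession = find_col(xdf, "STUDY ACCESSION", associations_path),
    chr_id = find_col(xdf, "CHR_ID", associations_path),
    chr_pos = parse_int_col(find_col(xdf, "CHR_POS", associations_path),
                            "CHR_POS", associations_path),
    strongest_snp_risk_allele = find_col(xdf, "STRONGEST SNP-RISK ALLELE",
                                         associations_path),
    reported_genes = find_col(xdf, "REPORTED GENE(S)", associations_path),
    p_value = p_value,
    stringsAsFactors = FALSE)
  associations <- cbind(associations, extras_of(
    xdf, c("STUDY ACCESSION", "CHR_ID", "CHR_POS", "STRONGEST SNP-RISK ALLELE",
           "REPORTED GENE(S)", "P-VALUE")))

  orphans <- setdiff(unique(associations$study_accession),
                     studies$study_accession)
  if (length(orphans)) {
    warning("association rows reference ", length(orphans),
            " accession(s) absent from Studies: ",
            paste(utils::head(orphans, 5L), collapse = ", "), call. = FALSE)
  }
  list(studies = studies, ancestries = ancestries, associations = associations)
}

#' Read a FinnGen release from a manifest plus local summary-statistics files
#'
#' @param manifest_path Manifest file: TSV with columns `phenocode`,
#'   `phenostring` (trait label) and `file`, or a JSON array of objects with
#'   those fields.
#' @param data_dir Directory holding the per-endpoint summary files named in
#'   the manifest.
#' @return List with one element per manifest endpoint (manifest order),
#'   each a list with `endpoint` (`endpoint_name`, `trait_label`,
#'   `summary_path`) and `variants` (typed `data.frame` with `chrom`, `pos`,
#'   `ref`, `alt`, `rsid`, `pval` plus remaining columns as text).
#'   Endpoints whose file is missing are skipped with a warning; duplicate
#'   endpoint names are a fatal error.
#' @export
read_finngen <- function(manifest_path, data_dir) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  if (grepl("\\.json$", manifest_path, ignore.case = TRUE)) {
    mdf <- jsonlite::fromJSON(manifest_path)
    if (length(mdf) == 0L) mdf <- data.frame(phenocode = character(),
                                             phenostring = character(),
                                             file = character())
  } else {
    mdf <- read_tsv_raw(manifest_path)
  }
  names(mdf) <- tolower(trimws(names(mdf)))
  for (req in c("phenocode", "phenostring", "file")) {
    if (!req %in% names(mdf)) {
      stop("format error: manifest lacks column '", req, "'")
    }
  }
  if (anyDuplicated(mdf$phenocode)) {
    stop("duplicate endpoint name(s) in manifest: ",
         paste(unique(mdf$phenocode[duplicated(mdf$phenocode)]),
               collapse = ", "))
  }
  out <- vector("list", 0L)
  for (i in seq_len(nrow(mdf))) {
    path <- file.path(data_dir, mdf$file[i])
    if (!file.exists(path)) {
      warning("summary file missing for endpoint '", mdf$phenocode[i],
              "': ", path, " (skipped)", call. = FALSE)
      next
    }
    vdf <- read_tsv_raw(path)
    chrom <- find_col(vdf, "#chrom", path)
    pos <- parse_int_col(find_col(vdf, "pos", path), "pos", path)
    pval <- parse_num_col(find_col(vdf, "pval", path, required = FALSE),
                          "pval", path)
    if (is.null(pval)) pval <- rep(NA_real_, length(pos))
    if (any(!is.na(pval) & (pval < 0 | pval > 1))) {
      stop("format error: pval outside [0,1] in ", path)
    }
    grab <- function(h) {
      v <- find_col(vdf, h, path, required = FALSE)
      if (is.null(v)) rep(NA_character_, length(chrom)) else v
    }
    variants <- data.frame(chrom = chrom, pos = pos, ref = grab("ref"),
                           alt = grab("alt"), rsid = grab("rsids"),
                           pval = pval, stringsAsFactors = FALSE)
    variants <- cbind(variants, extras_of(
      vdf, c("#chrom", "pos", "ref", "alt", "rsids", "pval")))
    out[[length(out) + 1L]] <- list(
      endpoint = list(endpoint_name = mdf$phenocode[i],
                      trait_label = mdf$phenostring[i],
                      summary_path = path),
      variants = variants)
  }
  out
}
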