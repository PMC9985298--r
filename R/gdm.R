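#' Genomic Data Model containers and file readers/writers
#'
#' The Genomic Data Model (GDM) represents a dataset as a collection of
#' samples, where each sample pairs a *region* file (genomic intervals with a
#' fixed coordinate part and data-type-specific variable attributes) with a
#' *metadata* file of free attribute-value pairs.  The two files share the
#' same identifier stem: `<sample_id>.gdm` and `<sample_id>.gdm.meta`.
#'
#' Coordinates are copied from sources without rebasing; `stop` is exclusive
#' by convention (a SNP at position p is the interval `[p, p+1)`), which is
#' documented in the serialized schema.
#'
#' @name gdm
NULL

GDM_FIXED_FIELDS <- data.frame(
  name = c("chrom", "start", "stop", "strand"),
  type = c("text", "integer", "integer", "text"),
  stringsAsFactors = FALSE
)

GDM_DATATYPES <- c("text", "integer", "float")

#' Declare a GDM region schema
#'
#' A region schema names the dataset format: a fixed coordinate part
#' (`chrom`, `start`, `stop`, `strand`, always first and in this order)
#' followed by an ordered list of typed variable fields.
#'
#' @param name Schema name (text).
#' @param variable_fields `data.frame` with columns `name` and `type`;
#'   `type` is one of `"text"`, `"integer"`, `"float"`.  May have zero rows.
#' @return An object of class `region_schema`.
#' @export
#' @examples
#' region_schema("snp", data.frame(name = "p_value", type = "float"))
region_schema <- function(name, variable_fields = NULL) {
  if (is.null(variable_fields)) {
    variable_fields <- data.frame(name = character(), type = character(),
                                  stringsAsFactors = FALSE)
  }
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  variable_fields <- as.data.frame(variable_fields, stringsAsFactors = FALSE)
  if (!all(c("name", "type") %in% names(variable_fields))) {
    stop("variable_fields must have columns 'name' and 'type'")
  }
  variable_fields <- variable_fields[, c("name", "type"), drop = FALSE]
  rownames(variable_fields) <- NULL
  bad <- setdiff(variable_fields$type, GDM_DATATYPES)
  if (length(bad)) {
    stop("unknown datatype token(s): ", paste(bad, collapse = ", "))
  }
  all_names <- c(GDM_FIXED_FIELDS$name, variable_fields$name)
  if (anyDuplicated(all_names)) {
    stop("duplicate field name(s): ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  }
  structure(list(name = name,
                 fixed_fields = GDM_FIXED_FIELDS,
                 variable_fields = variable_fields),
            class = "region_schema")
}

#' @export
print.region_schema <- function(x, ...) {
  cat("GDM region schema '", x$name, "': ", sep = "")
  cat(nrow(x$fixed_fields), "fixed +", nrow(x$variable_fields),
      "variable fields\n")
  flds <- rbind(cbind(x$fixed_fields, part = "fixed"),
                if (nrow(x$variable_fields))
                  cbind(x$variable_fields, part = "variable"))
  print(flds, row.names = FALSE)
  invisible(x)
}

schema_colnames <- function(schema) {
  c(schema$fixed_fields$name, schema$variable_fields$name)
}

r_type_for <- function(type) {
  switch(type, text = "character", integer = "integer", float = "numeric",
         stop("unknown datatype token: ", type))
}

#' Build an empty region table for a schema
#'
#' @param schema A [region_schema()].
#' @return Zero-row `data.frame` with one column per schema field, typed.
#' @export
empty_regions <- function(schema) {
  cols <- lapply(seq_len(nrow(schema$fixed_fields)), function(i) {
    vector(r_type_for(schema$fixed_fields$type[i]), 0L)
  })
  vcols <- lapply(seq_len(nrow(schema$variable_fields)), function(i) {
    vector(r_type_for(schema$variable_fields$type[i]), 0L)
  })
  out <- c(cols, vcols)
  names(out) <- schema_colnames(schema)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Construct a GDM sample
#'
#' @param sample_id Unique sample identifier (text, non-empty, usable as a
#'   file name stem).
#' @param regions `data.frame` of regions whose columns follow the schema
#'   order: `chrom`, `start`, `stop`, `strand`, then the variable fields.
#' @param metadata `data.frame` with character columns `attribute`, `value`.
#'   The same attribute may occur several times (multi-valued pairs); order
#'   is meaningful and preserved.
#' @param schema The [region_schema()] the regions conform to.
#' @return Object of class `gdm_sample`.
#' @export
gdm_sample <- function(sample_id, regions, metadata, schema) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  if (is.null(metadata) || nrow(metadata) == 0L) {
    metadata <- data.frame(attribute = character(), value = character(),
                           stringsAsFactors = FALSE)
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!all(c("attribute", "value") %in% names(metadata))) {
    stop("metadata must have columns 'attribute' and 'value'")
  }
  metadata <- metadata[, c("attribute", "value"), drop = FALSE]
  metadata$attribute <- as.character(metadata$attribute)
  metadata$value <- as.character(metadata$value)
  if (any(!nzchar(metadata$attribute))) stop("empty metadata attribute name")
  regions <- validate_regions(regions, schema)
  structure(list(sample_id = sample_id, regions = regions,
                 metadata = metadata, schema_name = schema$name),
            class = "gdm_sample")
}

validate_regions <- function(regions, schema) {
  if (is.null(regions)) regions <- empty_regions(schema)
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  want <- schema_colnames(schema)
  if (!identical(names(regions), want)) {
    stop("schema violation: region columns (",
         paste(names(regions), collapse = ","),
         ") do not match schema fields (", paste(want, collapse = ","), ")")
  }
  regions$chrom <- as.character(regions$chrom)
  regions$start <- as.integer(regions$start)
  regions$stop <- as.integer(regions$stop)
  regions$strand <- as.character(regions$strand)
  regions$strand[is.na(regions$strand) | !nzchar(regions$strand)] <- "*"
  if (nrow(regions)) {
    if (any(is.na(regions$start)) || any(is.na(regions$stop))) {
      stop("schema violation: non-numeric start/stop")
    }
    if (any(regions$stop <= regions$start)) {
      bad <- which(regions$stop <= regions$start)[1L]
      stop("coordinate error: stop <= start at region row ", bad)
    }
    if (!all(regions$strand %in% c("+", "-", "*"))) {
      stop("schema violation: strand must be one of +, -, *")
    }
  }
  for (i in seq_len(nrow(schema$variable_fields))) {
    nm <- schema$variable_fields$name[i]
    regions[[nm]] <- switch(schema$variable_fields$type[i],
                            text = as.character(regions[[nm]]),
                            integer = as.integer(regions[[nm]]),
                            float = as.numeric(regions[[nm]]))
  }
  rownames(regions) <- NULL
  regions
}

#' @export
print.gdm_sample <- function(x, ...) {
  cat("GDM sample '", x$sample_id, "' (schema '", x$schema_name, "'): ",
      nrow(x$regions), " regions, ", nrow(x$metadata), " metadata pairs\n",
      sep = "")
  invisible(x)
}

#' Construct a GDM dataset
#'
#' @param name Dataset name.
#' @param schema The single [region_schema()] every sample conforms to.
#' @param samples List of [gdm_sample()] objects with unique `sample_id`s.
#' @return Object of class `gdm_dataset`.
#' @export
gdm_dataset <- function(name, schema, samples = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (s in samples) {
    if (!identical(s$schema_name, schema$name)) {
      stop("sample '", s$sample_id, "' declares schema '", s$schema_name,
           "', dataset schema is '", schema$name, "'")
    }
  }
  names(samples) <- ids
  structure(list(name = name, schema = schema, samples = samples),
            class = "gdm_dataset")
}

#' @export
print.gdm_dataset <- function(x, ...) {
  cat("GDM dataset '", x$name, "': ", length(x$samples), " samples under schema '",
      x$schema$name, "'\n", sep = "")
  invisible(x)
}

# tab is the only separator; literal tabs/newlines in values become spaces so
# the writer is total
sanitize_cell <- function(x) gsub("[\t\r\n]+", " ", x)

format_gdm_value <- function(v) {
  out <- if (is.double(v)) {
    vapply(v, function(x) if (is.na(x)) "NA" else format(x, digits = 15,
                                                         scientific = FALSE,
                                                         trim = TRUE),
           character(1))
  } else {
    ifelse(is.na(v), "NA", as.character(v))
  }
  sanitize_cell(out)
}

#' Write one GDM sample as a paired region + metadata file
#'
#' The region file `<sample_id>.gdm` is a headerless TSV with columns in
#' schema order; the metadata file `<sample_id>.gdm.meta` is a two-column
#' TSV of (attribute, value) pairs, one per line, order preserved.
#'
#' @param sample A [gdm_sample()].
#' @param schema Its [region_schema()].
#' @param directory Output directory (created if missing).
#' @return Named character vector with elements `region` and `metadata`
#'   (the two file paths), invisibly.
#' @export
write_gdm_sample <- function(sample, schema, directory) {
  regions <- validate_regions(sample$regions, schema)
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) stop("cannot create directory: ", directory)
  }
  region_path <- file.path(directory, paste0(sample$sample_id, ".gdm"))
  meta_path <- file.path(directory, paste0(sample$sample_id, ".gdm.meta"))
  lines <- if (nrow(regions)) {
    cols <- lapply(regions, format_gdm_value)
    do.call(paste, c(cols, sep = "\t"))
  } else character()
  writeLines(lines, region_path, useBytes = TRUE)
  mlines <- if (nrow(sample$metadata)) {
    paste(sanitize_cell(sample$metadata$attribute),
          sanitize_cell(sample$metadata$value), sep = "\t")
  } else character()
  writeLines(mlines, meta_path, useBytes = TRUE)
  invisible(c(region = region_path, metadata = meta_path))
}

#' Read one GDM sample back from its paired files
#'
#' Inverse of [write_gdm_sample()]: `read_gdm_sample(write_gdm_sample(s))`
#' returns `s` field for field.  Duplicated metadata attributes are retained
#' in order (multi-valued pairs).
#'
#' @param region_path Path to the `.gdm` region file.
#' @param metadata_path Path to the `.gdm.meta` metadata file.
#' @param schema The [region_schema()] declaring the column layout.
#' @return A [gdm_sample()].
#' @export
read_gdm_sample <- function(region_path, metadata_path, schema) {
  if (!file.exists(region_path)) stop("region file not found: ", region_path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  want <- schema_colnames(schema)
  lines <- readLines(region_path)
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    arity <- lengths(parts)
    if (any(arity != length(want))) {
      bad <- which(arity != length(want))[1L]
      stop("schema violation: line ", bad, " has ", arity[bad],
           " columns, schema declares ", length(want))
    }
    mat <- do.call(rbind, parts)
    regions <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(regions) <- want
    for (nm in c("start", "stop")) {
      v <- suppressWarnings(as.integer(regions[[nm]]))
      if (anyNA(v)) {
        bad <- which(is.na(v))[1L]
        stop("parse error: non-numeric ", nm, " at line ", bad,
             " of ", region_path)
      }
      regions[[nm]] <- v
    }
  } else {
    regions <- empty_regions(schema)
  }
  mlines <- readLines(metadata_path)
  mlines <- mlines[nzchar(mlines)]
  if (length(mlines)) {
    mparts <- strsplit(mlines, "\t", fixed = TRUE)
    metadata <- data.frame(
      attribute = vapply(mparts, `[`, character(1), 1L),
      value = vapply(mparts, function(p) if (length(p) > 1L) p[2L] else "",
                     character(1)),
      stringsAsFactors = FALSE)
  } else {
    metadata <- NULL
  }
  sample_id <- sub("\\.gdm$", "", basename(region_path))
  gdm_sample(sample_id, regions, metadata, schema)
}

#' Serialize a region schema as a declarative XML document
#'
#' One `<field>` element per schema field in order, carrying `name`, `type`
#' and `part` (fixed or variable) attributes.  The document also records the
#' coordinate convention (stop-exclusive, coordinates copied from sources).
#'
#' @param schema A [region_schema()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gdm_schema <- function(schema, path) {
  doc <- xml2::xml_new_root("gdm_schema", name = schema$name,
                            coordinates = "source-copied, stop-exclusive")
  flds <- rbind(cbind(schema$fixed_fields, part = "fixed"),
                if (nrow(schema$variable_fields))
                  cbind(schema$variable_fields, part = "variable"))
  for (i in seq_len(nrow(flds))) {
    xml2::xml_add_child(doc, "field", name = flds$name[i],
                        type = flds$type[i], part = flds$part[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a region schema document written by [write_gdm_schema()]
#'
#' @param path Path to the XML schema document.
#' @return A [region_schema()].
#' @export
read_gdm_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  doc <- xml2::read_xml(path)
  name <- xml2::xml_attr(doc, "name")
  fields <- xml2::xml_find_all(doc, "field")
  df <- data.frame(
    name = xml2::xml_attr(fields, "name"),
    type = xml2::xml_attr(fields, "type"),
    part = xml2::xml_attr(fields, "part"),
    stringsAsFactors = FALSE)
  bad <- setdiff(df$type, GDM_DATATYPES)
  if (length(bad)) stop("unknown datatype token(s): ", paste(bad, collapse = ", "))
  fixed <- df[df$part == "fixed", c("name", "type")]
  rownames(fixed) <- NULL
  if (!identical(fixed, GDM_FIXED_FIELDS)) {
    stop("schema document fixed part must be chrom/start/stop/strand")
  }
  region_schema(name, df[df$part == "variable", c("name", "type")])
}

#' Write a whole GDM dataset to a directory
#'
#' Writes the schema document (`<dataset>.schema.xml`) plus one region and
#' one metadata file per sample.
#'
#' @param dataset A [gdm_dataset()].
#' @param directory Output directory.
#' @return `directory`, invisibly.
#' @export
write_gdm_dataset <- function(dataset, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  write_gdm_schema(dataset$schema,
                   file.path(directory, paste0(dataset$name, ".schema.xml")))
  for (s in dataset$samples) write_gdm_sample(s, dataset$schema, directory)
  invisible(directory)
}

#' Read a GDM dataset from a directory written by [write_gdm_dataset()]
#'
#' @param directory Directory holding one `*.schema.xml` plus paired
#'   `*.gdm` / `*.gdm.meta` files.
#' @param name Optional dataset name; defaults to the schema document stem.
#' @return A [gdm_dataset()].
#' @export
read_gdm_dataset <- function(directory, name = NULL) {
  schema_files <- list.files(directory, pattern = "\\.schema\\.xml$",
                             full.names = TRUE)
  if (length(schema_files) != 1L) {
    stop("expected exactly one *.schema.xml in ", directory)
  }
  schema <- read_gdm_schema(schema_files)
  if (is.null(name)) name <- sub("\\.schema\\.xml$", "", basename(schema_files))
  region_files <- sort(list.files(directory, pattern = "\\.gdm$",
                                  full.names = TRUE))
  samples <- lapply(region_files, function(rf) {
    read_gdm_sample(rf, paste0(rf, ".meta"), schema)
  })
  gdm_dataset(name, schema, samples)
}
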