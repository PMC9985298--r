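# Programmatic fixtures shared across test files.

test_schema <- function() {
  region_schema("test_snp", data.frame(
    name = c("rsid", "p_value"), type = c("text", "float"),
    stringsAsFactors = FALSE))
}

random_regions <- function(n, schema = test_schema()) {
  start <- sample.int(1e6, n)
  data.frame(chrom = paste0("chr", sample(1:5, n, replace = TRUE)),
             start = start, stop = start + sample(1:100, n, replace = TRUE),
             strand = sample(c("+", "-", "*"), n, replace = TRUE),
             rsid = paste0("rs", sample.int(1e6, n)),
             p_value = round(stats::runif(n), 6),
             stringsAsFactors = FALSE)
}

random_sample <- function(id, n_regions = 3L, n_meta = 4L,
                          schema = test_schema()) {
  meta <- data.frame(
    attribute = sample(c("trait", "pmid", "ancestry", "note"), n_meta,
                       replace = TRUE),
    value = replicate(n_meta, paste(sample(letters, 5), collapse = "")),
    stringsAsFactors = FALSE)
  gdm_sample(id, random_regions(n_regions, schema), meta, schema)
}

# A small random interval table for region-query oracle checks.
random_query_regions <- function(n, n_chrom = 3L, span = 5000L) {
  start <- sample.int(span, n, replace = TRUE)
  data.frame(chrom = paste0("chr", sample(seq_len(n_chrom), n, replace = TRUE)),
             start = start,
             stop = start + sample(1:50, n, replace = TRUE),
             strand = "*",
             stringsAsFactors = FALSE)
}
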