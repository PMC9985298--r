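#' Toy-scale interval queries over GDM regions
#'
#' Minimal demonstrations of the cross-dataset positional queries the
#' integrated GWAS datasets support in a multi-sample query engine: an
#' overlap-count map (how many experiment SNPs fall on each reference
#' region) and a bounded closest join (the nearest deletion within a
#' distance cutoff of each SNP).  Overlap and distance semantics are pinned
#' locally and documented as demo-grade: regions are stop-exclusive,
#' distance is the gap between intervals (0 when they overlap), and ties go
#' to the leftmost then smallest target.
#'
#' @name region_query
NULL

regions_to_granges <- function(df, seqlevels) {
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = df$start, end = df$stop - 1L))
}

#' Count experiment regions overlapping each reference region
#'
#' Overlap is `start < other.stop && stop > other.start` on the same
#' chromosome (half-open intervals).
#'
#' @param reference,experiment Region `data.frame`s (columns `chrom`,
#'   `start`, `stop`, ...), e.g. `sample$regions`.
#' @param min_count Keep only reference regions with at least this many
#'   overlaps (use `1` to mirror a `count > 0` filter; default 0 keeps all).
#' @return `reference` with an appended `count` column.
#' @export
map_count <- function(reference, experiment, min_count = 0L) {
  seqlevels <- unique(c(reference$chrom, experiment$chrom))
  if (!length(seqlevels)) seqlevels <- "chr_none"
  counts <- if (nrow(reference) == 0L) {
    integer()
  } else if (nrow(experiment) == 0L) {
    integer(nrow(reference))
  } else {
    GenomicRanges::countOverlaps(regions_to_granges(reference, seqlevels),
                                 regions_to_granges(experiment, seqlevels))
  }
  out <- reference
  out$count <- as.integer(counts)
  out[out$count >= min_count, , drop = FALSE]
}

#' Closest target within a distance bound, per anchor
#'
#' For each anchor region, the same-chromosome target with the minimal gap,
#' kept only when the gap is strictly below `max_distance`; overlapping
#' regions have distance 0.  Ties are broken by smallest target start, then
#' smallest target width.  Anchors with no qualifying target are omitted.
#'
#' @param anchors,targets Region `data.frame`s.
#' @param max_distance Distance bound in bp (`>= 0`).
#' @return `data.frame` with columns `anchor_chrom`, `anchor_start`,
#'   `anchor_stop`, `target_chrom`, `target_start`, `target_stop`,
#'   `distance`, one row per qualifying anchor in input order.
#' @export
closest_within <- function(anchors, targets, max_distance) {
  stopifnot(max_distance >= 0)
  empty <- data.frame(anchor_chrom = character(), anchor_start = integer(),
                      anchor_stop = integer(), target_chrom = character(),
                      target_start = integer(), target_stop = integer(),
                      distance = integer(), stringsAsFactors = FALSE)
  if (nrow(anchors) == 0L || nrow(targets) == 0L || max_distance == 0) {
    return(empty)
  }
  seqlevels <- unique(c(anchors$chrom, targets$chrom))
  a_gr <- regions_to_granges(anchors, seqlevels)
  t_gr <- regions_to_granges(targets, seqlevels)
  # candidate pairs within the bound (overlaps included), exact gaps locally
  hits <- GenomicRanges::findOverlaps(a_gr, t_gr,
                                      maxgap = ceiling(max_distance) - 1L)
  if (length(hits) == 0L) return(empty)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  dist <- pmax(0L, pmax(anchors$start[qh], targets$start[sh]) -
                 pmin(anchors$stop[qh], targets$stop[sh]))
  keep <- dist < max_distance
  qh <- qh[keep]; sh <- sh[keep]; dist <- dist[keep]
  if (!length(qh)) return(empty)
  # minimal gap per anchor; ties to the leftmost then smallest target
  ord <- order(qh, dist, targets$start[sh], targets$stop[sh] - targets$start[sh])
  qh <- qh[ord]; sh <- sh[ord]; dist <- dist[ord]
  first <- !duplicated(qh)
  qh <- qh[first]; sh <- sh[first]; dist <- dist[first]
  data.frame(anchor_chrom = anchors$chrom[qh],
             anchor_start = anchors$start[qh],
             anchor_stop = anchors$stop[qh],
             target_chrom = targets$chrom[sh],
             target_start = targets$start[sh],
             target_stop = targets$stop[sh],
             distance = as.integer(dist), stringsAsFactors = FALSE)
}
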