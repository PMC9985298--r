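# Independent oracles used across tests.

# Exhaustive minimum-cost alignment by plain recursion over all edit
# scripts (match/substitute, delete query word, insert label word,
# transpose adjacent cross-equal pair).  No memoisation, no DP table:
# independent of the implementation under test.
oracle_word_distance <- function(q, l) {
  q <- tolower(q)
  l <- tolower(l)
  n <- length(q)
  m <- length(l)
  rec <- function(i, j) {
    if (i > n && j > m) return(0)
    best <- Inf
    if (i <= n && j <= m) {
      best <- min(best, rec(i + 1L, j + 1L) + (if (q[i] == l[j]) 0 else 2.5))
    }
    if (i <= n) best <- min(best, rec(i + 1L, j) + 2)
    if (j <= m) best <- min(best, rec(i, j + 1L) + 1)
    if (i + 1L <= n && j + 1L <= m && q[i] == l[j + 1L] && q[i + 1L] == l[j]) {
      best <- min(best, rec(i + 2L, j + 2L) + 0.5)
    }
    best
  }
  rec(1L, 1L)
}

# The distance depends only on the token-equality pattern of the pair, so
# exhaustive sweeps canonicalise each pair (relabel tokens by first
# occurrence) and cache the oracle value per pattern.
make_pattern_memo <- function() new.env(parent = emptyenv())

memo_oracle_distance <- function(q, l, memo) {
  both <- c(q, l)
  canon <- match(both, unique(both))
  key <- paste(length(q), paste(canon, collapse = "."), sep = ":")
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  val <- oracle_word_distance(q, l)
  memo[[key]] <- val
  val
}

# All token lists of length 1..max_len over the given alphabet.
all_token_lists <- function(alphabet, max_len) {
  out <- list()
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len),
                      list(stringsAsFactors = FALSE)))
    for (r in seq_len(nrow(grid))) {
      out[[length(out) + 1L]] <- as.character(unlist(grid[r, ]))
    }
  }
  out
}

# Candidate-annotation table builder for ontology-set selection fixtures:
# cover is a named list ontology -> covered value names (all match score 10).
sel_fixture <- function(cover) {
  do.call(rbind, lapply(names(cover), function(o) {
    if (!length(cover[[o]])) return(NULL)
    data.frame(ontology = o, raw = cover[[o]], match_score = 10,
               stringsAsFactors = FALSE)
  }))
}

# Exhaustive subset search: smallest ontology subsets reaching the coverage
# target, or the best-coverage subsets if the target is unreachable.
exhaustive_best_set <- function(values, ann, target) {
  ontos <- unique(ann$ontology)
  best <- NULL
  for (k in seq_along(ontos)) {
    combos <- utils::combn(ontos, k, simplify = FALSE)
    covs <- vapply(combos, function(set) {
      length(unique(ann$raw[ann$ontology %in% set])) / length(values)
    }, numeric(1))
    ok <- covs >= target
    if (any(ok)) {
      return(list(size = k, sets = combos[ok]))
    }
    best <- list(size = k, sets = combos[which.max(covs)], cov = max(covs))
  }
  best
}

# Brute-force all-pairs region overlap counts (half-open intervals).
brute_map_count <- function(reference, experiment) {
  vapply(seq_len(nrow(reference)), function(i) {
    sum(experiment$chrom == reference$chrom[i] &
          experiment$start < reference$stop[i] &
          experiment$stop > reference$start[i])
  }, integer(1))
}

# Brute-force closest target per anchor under the gap definition
# (0 when overlapping), with leftmost-then-smallest tie-break.
brute_closest_within <- function(anchors, targets, max_distance) {
  rows <- list()
  for (i in seq_len(nrow(anchors))) {
    cand <- targets[targets$chrom == anchors$chrom[i], , drop = FALSE]
    if (!nrow(cand)) next
    gap <- pmax(0L, pmax(anchors$start[i], cand$start) -
                  pmin(anchors$stop[i], cand$stop))
    ok <- gap < max_distance
    if (!any(ok)) next
    cand <- cand[ok, , drop = FALSE]
    gap <- gap[ok]
    ord <- order(gap, cand$start, cand$stop - cand$start)
    k <- ord[1L]
    rows[[length(rows) + 1L]] <- data.frame(
      anchor_chrom = anchors$chrom[i], anchor_start = anchors$start[i],
      anchor_stop = anchors$stop[i], target_chrom = cand$chrom[k],
      target_start = cand$start[k], target_stop = cand$stop[k],
      distance = as.integer(gap[k]), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(anchor_chrom = character(), anchor_start = integer(),
                      anchor_stop = integer(), target_chrom = character(),
                      target_start = integer(), target_stop = integer(),
                      distance = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
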