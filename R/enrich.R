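#' Semantic enrichment of phenotypic trait names
#'
#' Trait values are annotated with ontology terms through a word-level
#' alignment distance: labels are tokenized into lowercase words and aligned
#' globally, where a matching word costs 0, a swap of two consecutive words
#' 0.5, a label-only word (insertion) 1, a query-only word (deletion) 2 and
#' a mismatch 2.5.  The `match_score` subtracts this distance from an
#' initial score of 10 (preferred label) or 9 (synonym), so pref-label
#' matches outrank synonym matches by construction.
#'
#' Ontologies are then scored by `coverage` (fraction of raw values they
#' annotate), externally supplied `acceptance` (community trust) and
#' `suitability` (coverage times the mean match score of their
#' annotations); each candidate annotation gets an `annotation_score` equal
#' to its match score times a linear combination of suitability and
#' acceptance, whose weights are recovered by least squares from a bundled
#' exemplar table.  A greedy pass selects a small ordered ontology set until
#' a coverage target (default 0.85) or a fixed point is reached.
#'
#' @name enricher
NULL

#' Tokenize a label for word-level alignment
#'
#' Lowercases, trims, splits on whitespace, and strips punctuation from the
#' edges of each token while keeping internal punctuation (so
#' `"magnesium:creatinine"` and `"pre-eclampsia"` stay single tokens but
#' `"Schizophrenia,"` loses its comma).
#'
#' @param x A character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize_label <- function(x) {
  x <- tolower(trimws(x))
  toks <- strsplit(x, "[[:space:]]+")[[1L]]
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks[nzchar(toks)]
}

#' Parse a raw trait value into one or more normalized parsed values
#'
#' Comma-separated raw values are split into one parsed value per segment
#' (long multi-trait expressions are common in source dumps); each segment
#' is lowercased, trimmed and whitespace-collapsed.
#'
#' @param raw Raw trait value (non-empty character scalar).
#' @return List of `parsed_value` objects, each with fields `raw`, `parsed`
#'   and `tokens`.  An all-punctuation raw value yields an empty list with a
#'   warning.
#' @export
#' @examples
#' parse_raw_value("height, weight")
parse_raw_value <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  segs <- strsplit(raw, ",", fixed = TRUE)[[1L]]
  out <- list()
  for (s in segs) {
    toks <- tokenize_label(s)
    if (!length(toks)) next
    out[[length(out) + 1L]] <- structure(
      list(raw = raw, parsed = paste(toks, collapse = " "), tokens = toks),
      class = "parsed_value")
  }
  if (!length(out)) {
    warning("raw value '", raw, "' contains no alphanumeric tokens",
            call. = FALSE)
  }
  out
}

#' Word-level global alignment distance
#'
#' Minimal-cost order-respecting alignment of two token lists under the
#' costs: equal tokens (case-insensitive) 0; transposition of two adjacent
#' words 0.5; label-only token (insertion) 1; query-only token (deletion) 2;
#' substitution 2.5.  Computed by dynamic programming with an adjacent
#' transposition extension, so deletions are minimized and swaps are
#' preferred to indels or mismatches.
#'
#' @param query_tokens Tokens of the (parsed) trait value.
#' @param label_tokens Tokens of the ontology label.
#' @return Nonnegative distance, a multiple of 0.5.
#' @export
#' @examples
#' word_distance(c("anorexia", "nervosa"), "anorexia")        # deletion: 2
#' word_distance("sneeze", c("peroutka", "sneeze"))           # insertion: 1
#' word_distance(c("a", "b"), c("b", "a"))                    # swap: 0.5
word_distance <- function(query_tokens, label_tokens) {
  q <- tolower(as.character(query_tokens))
  l <- tolower(as.character(label_tokens))
  n <- length(q)
  m <- length(l)
  d <- matrix(0, n + 1L, m + 1L)
  d[, 1L] <- (0:n) * 2      # dropping a query word is a deletion
  d[1L, ] <- (0:m) * 1      # an extra label word is an insertion
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- min(d[i, j] + (if (q[i] == l[j]) 0 else 2.5),
                  d[i, j + 1L] + 2,
                  d[i + 1L, j] + 1)
      if (i > 1L && j > 1L && q[i] == l[j - 1L] && q[i - 1L] == l[j]) {
        best <- min(best, d[i - 1L, j - 1L] + 0.5)
      }
      d[i + 1L, j + 1L] <- best
    }
  }
  d[n + 1L, m + 1L]
}

#' Construct an ontology term record
#'
#' @param ontology Short ontology name (e.g. `"EFO"`).
#' @param ontology_id Term identifier unique within the ontology.
#' @param pref_label Preferred label.
#' @param synonyms Character vector of alternative labels.
#' @param description,iri Free-text description and term IRI.
#' @param xrefs Character vector of cross-references.
#' @param parents,children Lists of `list(ontology, ontology_id, kind)`
#'   links, `kind` one of `"is_a"`, `"part_of"`.
#' @return Object of class `term_record`.
#' @export
term_record <- function(ontology, ontology_id, pref_label,
                        synonyms = character(), description = NA_character_,
                        iri = NA_character_, xrefs = character(),
                        parents = list(), children = list()) {
  stopifnot(nzchar(ontology), nzchar(ontology_id), nzchar(pref_label))
  structure(list(ontology = ontology, ontology_id = ontology_id,
                 pref_label = pref_label, synonyms = as.character(synonyms),
                 description = description, iri = iri,
                 xrefs = as.character(xrefs), parents = parents,
                 children = children),
            class = "term_record")
}

as_parsed_value <- function(x) {
  if (inherits(x, "parsed_value")) return(x)
  pv <- parse_raw_value(x)
  if (length(pv) != 1L) {
    stop("value '", x, "' parses to ", length(pv),
         " segments; pass one parsed_value explicitly")
  }
  pv[[1L]]
}

#' Score one term against one parsed value
#'
#' The best candidate over the preferred label (initial score 10) and every
#' synonym (initial score 9), each penalized by [word_distance()].  Ties are
#' broken preferring the preferred-label basis, then the lexicographically
#' smallest label.
#'
#' @param parsed A `parsed_value` (or a character scalar parsing to one).
#' @param term A [term_record()].
#' @return Object of class `annotation_candidate` with fields `raw`,
#'   `parsed`, `ontology`, `ontology_id`, `basis` (`"P"` or `"S"`),
#'   `matched_label`, `distance`, `match_score`.
#' @export
match_score <- function(parsed, term) {
  parsed <- as_parsed_value(parsed)
  labels <- c(term$pref_label, term$synonyms)
  basis <- c("P", rep("S", length(term$synonyms)))
  initial <- c(10, rep(9, length(term$synonyms)))
  dist <- vapply(labels, function(l) {
    word_distance(parsed$tokens, tokenize_label(l))
  }, numeric(1), USE.NAMES = FALSE)
  score <- initial - dist
  ord <- order(-score, basis, tolower(labels))
  k <- ord[1L]
  structure(list(raw = parsed$raw, parsed = parsed$parsed,
                 ontology = term$ontology, ontology_id = term$ontology_id,
                 basis = basis[k], matched_label = labels[k],
                 distance = dist[k], match_score = score[k]),
            class = "annotation_candidate")
}

#' @export
print.annotation_candidate <- function(x, ...) {
  cat(sprintf("'%s' -> %s %s ('%s', %s): match %.1f (%s)\n",
              x$parsed, x$ontology, x$ontology_id, x$matched_label,
              ifelse(x$basis == "P", "pref_label", "synonym"),
              x$match_score, x$basis))
  invisible(x)
}

candidates_to_df <- function(cands) {
  if (!length(cands)) {
    return(data.frame(raw = character(), parsed = character(),
                      ontology = character(), ontology_id = character(),
                      basis = character(), matched_label = character(),
                      distance = numeric(), match_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(cands, function(c) {
    as.data.frame(unclass(c), stringsAsFactors = FALSE)
  }))
}

#' Per-ontology coverage and suitability
#'
#' `coverage` is the fraction of the raw values that the ontology annotates;
#' `suitability` multiplies the coverage by the mean match score of all the
#' ontology's annotations, so annotating through preferred labels scores
#' higher than through synonyms.
#'
#' @param annotations `data.frame` with at least columns `ontology`, `raw`,
#'   `match_score` (e.g. rbind of [match_score()] candidates).
#' @param n_raw_values Total number of raw values submitted for annotation.
#' @param acceptance Named numeric vector of per-ontology acceptance scores
#'   in `[0,1]` (an external input: how trusted the ontology is).  Every
#'   ontology appearing in `annotations` must be present.
#' @return `data.frame` with columns `ontology`, `coverage`, `acceptance`,
#'   `suitability`.
#' @export
ontology_scores <- function(annotations, n_raw_values, acceptance) {
  ontos <- sort(unique(annotations$ontology))
  missing <- setdiff(ontos, names(acceptance))
  if (length(missing)) {
    stop("no acceptance score for ontolog", if (length(missing) > 1) "ies" else "y",
         ": ", paste(missing, collapse = ", "))
  }
  out <- data.frame(ontology = ontos, coverage = numeric(length(ontos)),
                    acceptance = numeric(length(ontos)),
                    suitability = numeric(length(ontos)),
                    stringsAsFactors = FALSE)
  for (k in seq_along(ontos)) {
    sub <- annotations[annotations$ontology == ontos[k], , drop = FALSE]
    cov <- length(unique(sub$raw)) / n_raw_values
    out$coverage[k] <- cov
    out$acceptance[k] <- unname(acceptance[ontos[k]])
    out$suitability[k] <- cov * sum(sub$match_score) / nrow(sub)
  }
  out
}

#' Overall annotation score
#'
#' `match_score * (w_suit * suitability + w_acc * acceptance)`, the quantity
#' used to rank candidate annotations across ontologies.
#'
#' @param match_score,suitability,acceptance Numeric (vectorized).
#' @param weights Numeric length-2 vector `c(suit = ..., acc = ...)`; both
#'   nonnegative.  Defaults to [default_annotation_weights()].
#' @return Numeric annotation score(s); report with 2 decimals.
#' @export
annotation_score <- function(match_score, suitability, acceptance,
                             weights = default_annotation_weights()) {
  if (length(weights) != 2L || any(is.na(weights)) || any(weights < 0)) {
    stop("weights must be two nonnegative numbers (suit, acc)")
  }
  match_score * (weights[[1L]] * suitability + weights[[2L]] * acceptance)
}

#' Recover the annotation-score weights by least squares
#'
#' Solves for `(w_suit, w_acc)` minimizing the squared error between
#' `match * (w_suit * suit + w_acc * acc)` and the given annotation scores.
#'
#' @param rows `data.frame` with columns `match_score`, `suitability`,
#'   `acceptance`, `annotation_score` (at least two linearly independent
#'   rows).
#' @return Named numeric vector `c(suit = ..., acc = ...)`.
#' @export
fit_weights <- function(rows) {
  X <- cbind(suit = rows$match_score * rows$suitability,
             acc = rows$match_score * rows$acceptance)
  if (nrow(X) < 2L || qr(X)$rank < 2L) {
    stop("need at least two linearly independent rows to fit weights")
  }
  fit <- stats::lm.fit(X, rows$annotation_score)
  stats::setNames(fit$coefficients, c("suit", "acc"))
}

#' Bundled exemplar annotation table
#'
#' A curated excerpt of trait annotations (parsed value, matched term and
#' label, basis, match score, ontology suitability and acceptance, final
#' annotation score) shipped with the package.  It anchors the default
#' annotation-score weights and the regression tests of the scoring
#' pipeline.
#'
#' @return `data.frame`, one row per exemplar annotation.
#' @export
annotation_examples <- function() {
  utils::read.delim(system.file("extdata", "annotation_examples.tsv",
                                package = "gdmgwas", mustWork = TRUE),
                    colClasses = c(rep("character", 5), rep("numeric", 4)))
}

#' Default annotation-score weights
#'
#' Least-squares fit of [fit_weights()] over [annotation_examples()],
#' recomputed at call time (cached for the session).
#'
#' @return Named numeric vector `c(suit = ..., acc = ...)`.
#' @export
default_annotation_weights <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fit_weights(annotation_examples())
    cache
  }
})

#' Greedy selection of a small ontology set under a coverage target
#'
#' Ontologies are ranked (by suitability or coverage); the first annotates
#' as many raw values as it can, each following ontology only the values
#' left unmatched, until the accumulated coverage reaches `coverage_target`
#' or no remaining ontology makes progress (the coverage fixed point).
#'
#' Set metrics are computed over the per-value annotations actually used:
#' `set_coverage` is the covered fraction of raw values; `set_score` the
#' mean match score of the annotated values weighted by their ontology's
#' acceptance; `set_suitability` the suitability formula applied to the
#' union of used annotations.
#'
#' @param values Character vector of distinct raw values to cover.
#' @param annotations `data.frame` of candidate annotations (columns
#'   `ontology`, `raw`, `match_score`; best candidate per value/ontology).
#' @param acceptance Named per-ontology acceptance map.
#' @param coverage_target Coverage at which selection stops (default 0.85).
#' @param rank_by `"suitability"` (default) or `"coverage"`.
#' @return List with `ontologies` (ordered chosen set), `set_coverage`,
#'   `set_score`, `set_suitability`, and `assignment` (`data.frame` of the
#'   per-value annotation used).
#' @export
select_ontology_set <- function(values, annotations, acceptance,
                                coverage_target = 0.85,
                                rank_by = c("suitability", "coverage")) {
  rank_by <- match.arg(rank_by)
  if (!length(unique(annotations$ontology))) {
    stop("no ontologies to select from")
  }
  scores <- ontology_scores(annotations, length(values), acceptance)
  ranked <- scores$ontology[order(-scores[[rank_by]], scores$ontology)]
  chosen <- character()
  assignment <- annotations[0, , drop = FALSE]
  covered <- character()
  for (onto in ranked) {
    if (length(chosen) && length(covered) / length(values) >= coverage_target) {
      break
    }
    sub <- annotations[annotations$ontology == onto &
                         annotations$raw %in% setdiff(values, covered), ,
                       drop = FALSE]
    if (!nrow(sub)) next
    # one annotation per newly covered value: the ontology's best
    sub <- sub[order(sub$raw, -sub$match_score), , drop = FALSE]
    sub <- sub[!duplicated(sub$raw), , drop = FALSE]
    chosen <- c(chosen, onto)
    covered <- c(covered, sub$raw)
    assignment <- rbind(assignment, sub)
  }
  set_coverage <- length(covered) / length(values)
  if (nrow(assignment)) {
    acc_used <- unname(acceptance[assignment$ontology])
    set_score <- mean(assignment$match_score * acc_used)
    set_suitability <- set_coverage *
      sum(assignment$match_score) / nrow(assignment)
  } else {
    set_score <- 0
    set_suitability <- 0
  }
  list(ontologies = chosen, set_coverage = set_coverage,
       set_score = set_score, set_suitability = set_suitability,
       assignment = assignment)
}
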