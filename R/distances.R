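# Rank distance on rankings and strings, plus Hamming and Levenshtein
# comparators. Positions are 1-based throughout.

#' DNA alphabet
#'
#' The four-letter nucleotide alphabet used by the genetic algorithms and
#' the FASTA readers. Characters outside the configured alphabet are a hard
#' error everywhere in the package; IUPAC ambiguity codes are not mapped.
#'
#' @return Character vector `c("A","C","G","T")`.
#' @export
dna_alphabet <- function() c("A", "C", "G", "T")

# split a length-1 string into single characters
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# map a string to 0-based alphabet codes; errors name the offending
# character and its 1-based position
.string_codes <- function(s, alphabet) {
  cs <- .chars(s)
  codes <- match(cs, alphabet)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop(sprintf("character '%s' at position %d is not in the alphabet {%s}",
                 cs[bad], bad, paste(alphabet, collapse = ",")),
         call. = FALSE)
  }
  codes - 1L
}

.check_string <- function(s, arg = "s") {
  if (!is.character(s) || length(s) != 1L || is.na(s))
    stop(sprintf("'%s' must be a single string", arg), call. = FALSE)
  invisible(s)
}

#' Construct a ranking
#'
#' A ranking is an ordered list of distinct objects; the object listed first
#' has position 1 (the highest rank). Rankings over a subset of a universe
#' are partial rankings and are accepted everywhere.
#'
#' @param items Vector of distinct items (coerced to character).
#' @return An object of class `"ranking"`: the item vector, with positions
#'   implied by order.
#' @examples
#' ranking(c("a", "b", "c"))
#' @export
ranking <- function(items) {
  items <- as.character(items)
  if (length(items) == 0L) stop("a ranking needs at least one item")
  if (anyDuplicated(items)) stop("ranking items must be distinct")
  structure(items, class = "ranking")
}

#' @export
print.ranking <- function(x, ...) {
  cat("<ranking> ", paste(unclass(x), collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Annotate a string with occurrence indices
#'
#' Tags the i-th occurrence of each letter with index i, so every annotated
#' symbol is unique and the string becomes a ranking over symbol/index
#' pairs. For example `"alibaba"` becomes a1 l1 i1 b1 a2 b2 a3.
#'
#' @param s A non-empty string.
#' @return An object of class `"annotated_string"` with fields `source`,
#'   `letter` (character vector) and `occ` (integer occurrence indices).
#' @examples
#' annotate("alibaba")
#' @export
annotate <- function(s) {
  .check_string(s)
  if (nchar(s) == 0L) stop("cannot annotate an empty string")
  letter <- .chars(s)
  occ <- stats::ave(seq_along(letter), letter, FUN = seq_along)
  structure(list(source = s, letter = letter, occ = as.integer(occ)),
            class = "annotated_string")
}

#' @export
print.annotated_string <- function(x, ...) {
  cat("<annotated_string> ",
      paste0(x$letter, x$occ, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Convert an annotated string to a ranking
#'
#' @param x An `annotated_string`.
#' @return A [ranking()] over the annotated symbols, in string order. Symbol
#'   labels are `letter.occurrence`, e.g. `"a.2"`.
#' @export
as_ranking <- function(x) {
  stopifnot(inherits(x, "annotated_string"))
  ranking(paste0(x$letter, ".", x$occ))
}

#' Rank distance between two rankings
#'
#' An item at position p in a ranking of length n has order `n + 1 - p`
#' (the top item has the highest order); an item absent from a ranking has
#' order 0 there. The rank distance is the sum, over the union of the two
#' item sets, of the absolute difference of an item's orders -- the L1
#' distance between the two order vectors. Partial rankings are allowed;
#' for two full rankings of the same universe this is the Spearman
#' footrule.
#'
#' @param sigma,tau Objects created by [ranking()] (or plain character
#'   vectors of distinct items).
#' @return Non-negative number.
#' @examples
#' rank_distance_rankings(ranking(c("a","b","c")), ranking(c("c","b","a")))
#' @export
rank_distance_rankings <- function(sigma, tau) {
  s <- as.character(sigma); t <- as.character(tau)
  ns <- length(s); nt <- length(t)
  ord_s <- ns + 1L - seq_len(ns)            # orders of sigma's items
  ord_in_t <- nt + 1L - match(s, t)         # their orders in tau (NA if absent)
  ord_in_t[is.na(ord_in_t)] <- 0L
  d <- sum(abs(ord_s - ord_in_t))
  only_t <- is.na(match(t, s))
  d + sum((nt + 1L - seq_len(nt))[only_t])  # items present only in tau
}

#' Rank distance between two strings (definitional path)
#'
#' Extends each string to a ranking of occurrence-annotated symbols and
#' applies [rank_distance_rankings()]. The i-th occurrence of a letter in
#' one string pairs with the i-th occurrence of the same letter in the
#' other; for equal-length strings a paired symbol contributes the gap
#' between its two positions and an unpaired one its order `n + 1 - p`.
#' The distance is symmetric, is zero exactly when the strings are equal,
#' and is defined for strings of unequal length.
#'
#' @param x,y Non-empty strings over any finite alphabet.
#' @return Non-negative number.
#' @seealso [rank_distance_linear()] for the fast path used by the genetic
#'   algorithms.
#' @examples
#' rank_distance("AACG", "ACGA")  # 4
#' @export
rank_distance <- function(x, y) {
  rank_distance_rankings(as_ranking(annotate(x)), as_ranking(annotate(y)))
}

#' Rank distance between two strings (linear-time path)
#'
#' Computes the same value as [rank_distance()] without building annotation
#' objects: one pass per string records, per letter, the list of occurrence
#' positions, and matched occurrences are paired in order. Runs in time
#' linear in the string lengths for a fixed alphabet.
#'
#' @param x,y Strings over `alphabet`.
#' @param alphabet Character vector of allowed letters; defaults to the
#'   letters present in `x` and `y`.
#' @return Non-negative number, identical to `rank_distance(x, y)`.
#' @export
rank_distance_linear <- function(x, y, alphabet = NULL) {
  .check_string(x, "x"); .check_string(y, "y")
  if (is.null(alphabet))
    alphabet <- sort(unique(c(.chars(x), .chars(y))))
  .cpp_rank_distance(.string_codes(x, alphabet), .string_codes(y, alphabet),
                     length(alphabet))
}

#' Hamming distance
#'
#' Number of positions where two equal-length strings differ. Unequal
#' lengths are an error, never padded.
#'
#' @param x,y Strings of equal length.
#' @return Non-negative number.
#' @export
hamming_distance <- function(x, y) {
  .check_string(x, "x"); .check_string(y, "y")
  if (nchar(x) != nchar(y))
    stop("Hamming distance requires equal-length strings", call. = FALSE)
  a <- utf8ToInt(x); b <- utf8ToInt(y)
  sum(a != b)
}

#' Levenshtein (edit) distance
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions transforming one string into the other, all at unit cost.
#'
#' @param x,y Strings (possibly empty, possibly of unequal length).
#' @return Non-negative number.
#' @export
levenshtein_distance <- function(x, y) {
  .check_string(x, "x"); .check_string(y, "y")
  .cpp_levenshtein(utf8ToInt(x), utf8ToInt(y))
}

# metric registry -----------------------------------------------------------

.metrics <- c("rank", "hamming", "levenshtein")

.check_metric <- function(metric) {
  match.arg(metric, .metrics)
}

#' Does a metric require equal-length strings?
#'
#' @param metric One of `"rank"`, `"hamming"`, `"levenshtein"`.
#' @return Logical. As used by the closest-string search, rank and Hamming
#'   compare equal-length strings; Levenshtein does not require it.
#' @export
metric_requires_equal_length <- function(metric) {
  metric <- .check_metric(metric)
  metric %in% c("rank", "hamming")
}

#' Distance between two strings under a named metric
#'
#' Dispatches to [rank_distance_linear()], [hamming_distance()] or
#' [levenshtein_distance()].
#'
#' @inheritParams rank_distance_linear
#' @param metric One of `"rank"`, `"hamming"`, `"levenshtein"`.
#' @return Non-negative number.
#' @export
string_distance <- function(x, y, metric = "rank", alphabet = NULL) {
  metric <- .check_metric(metric)
  switch(metric,
         rank        = rank_distance_linear(x, y, alphabet),
         hamming     = hamming_distance(x, y),
         levenshtein = levenshtein_distance(x, y))
}

#' Maximum distance from a candidate to a set of strings
#'
#' The radius of the candidate with respect to the input set: the largest
#' distance from `s` to any input. This is the closest-string objective the
#' genetic algorithm minimises (smaller is better).
#'
#' @param s Candidate string.
#' @param inputs Non-empty character vector (or list) of input strings.
#' @param metric One of `"rank"`, `"hamming"`, `"levenshtein"`.
#' @param alphabet Optional alphabet for the rank metric.
#' @return Non-negative number.
#' @export
max_distance_to_set <- function(s, inputs, metric = "rank", alphabet = NULL) {
  inputs <- as.character(inputs)
  if (length(inputs) == 0L) stop("'inputs' must be non-empty")
  max(vapply(inputs, function(t) string_distance(s, t, metric, alphabet),
             numeric(1)))
}
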