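# Encoding between strings and permutations of annotated-symbol ranks.
# Canonical numbering: annotated symbols sorted by letter, then occurrence
# index, receive ids 1..m; a candidate string with the reference letter
# composition is then exactly a permutation of 1..m.

#' Build a composition map from a reference string
#'
#' Annotates the reference with occurrence indices and assigns each
#' annotated symbol a unique id in 1..m, in canonical order (letters
#' alphabetical, occurrence indices ascending within a letter). Every
#' string with the same letter composition as the reference encodes to a
#' permutation of 1..m under this map, and every permutation decodes to
#' such a string.
#'
#' @param reference Non-empty string whose letter composition defines the
#'   search space.
#' @return An object of class `"composition_map"` with fields `letters`
#'   (character vector of length m in canonical order, so `letters[id]` is
#'   the letter of symbol `id`), `occ` (its occurrence indices) and `id_of`
#'   (named integer vector keyed by `"letter.occ"`).
#' @examples
#' m <- composition_map("alibaba")
#' decode_string(seq_len(7), m)  # canonical string "aaabbil"
#' @export
composition_map <- function(reference) {
  ann <- annotate(reference)
  ord <- order(ann$letter, ann$occ, method = "radix")
  letters <- ann$letter[ord]
  occ <- ann$occ[ord]
  id_of <- seq_along(letters)
  names(id_of) <- paste0(letters, ".", occ)
  structure(list(letters = letters, occ = occ, id_of = id_of,
                 size = length(letters)),
            class = "composition_map")
}

#' @export
print.composition_map <- function(x, ...) {
  cat(sprintf("<composition_map> %d symbols: %s\n", x$size,
              paste0(x$letters, x$occ, collapse = " ")))
  invisible(x)
}

#' Encode a string as a permutation chromosome
#'
#' @param s String with exactly the map's letter composition.
#' @param map A [composition_map()].
#' @return Integer permutation of 1..m; entry i is the id of the annotated
#'   symbol at position i of `s`. `decode_string(encode_string(s, map), map)`
#'   recovers `s`.
#' @export
encode_string <- function(s, map) {
  stopifnot(inherits(map, "composition_map"))
  ann <- annotate(s)
  keys <- paste0(ann$letter, ".", ann$occ)
  perm <- unname(map$id_of[keys])
  if (length(perm) != map$size || anyNA(perm))
    stop("string composition does not match the composition map",
         call. = FALSE)
  perm
}

#' Decode a permutation chromosome to a string
#'
#' @param perm Integer permutation of 1..m.
#' @param map A [composition_map()] with m symbols.
#' @return String of length m; position i holds the letter of symbol
#'   `perm[i]`. The identity permutation decodes to the canonical string of
#'   the composition (letters sorted).
#' @export
decode_string <- function(perm, map) {
  stopifnot(inherits(map, "composition_map"))
  if (length(perm) != map$size)
    stop("chromosome length does not match the composition map",
         call. = FALSE)
  paste(map$letters[perm], collapse = "")
}

.check_perm <- function(perm, arg = "perm") {
  m <- length(perm)
  if (m == 0L || !all(sort(perm) == seq_len(m)))
    stop(sprintf("'%s' must be a permutation of 1..m", arg), call. = FALSE)
  as.integer(perm)
}
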