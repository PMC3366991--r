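# Order-based crossovers and swap mutation on permutation chromosomes.
# Each crossover keeps a block of one parent in place and fills the
# remaining positions with the missing values in the relative order they
# occur in the other parent, so children are always valid permutations.

.fill_by_order <- function(keep, other) other[!(other %in% keep)]

#' Prefix-preserving order crossover
#'
#' Child 1 keeps the first `cut` entries of `c1` and completes the
#' permutation with the remaining values in the relative order they occur
#' in `c2`; child 2 is the symmetric construction.
#'
#' @param c1,c2 Integer permutations of 1..m (equal m).
#' @param cut Cut point, `1 <= cut <= m - 1`.
#' @return List of two integer permutations `child1`, `child2`.
#' @examples
#' crossover_prefix(c(7,3,2,9,1,5,8,6,4), c(4,8,1,6,3,7,9,5,2), 4)
#' @export
crossover_prefix <- function(c1, c2, cut) {
  c1 <- .check_perm(c1, "c1"); c2 <- .check_perm(c2, "c2")
  m <- length(c1)
  if (length(c2) != m) stop("parents must have equal length")
  if (cut < 1L || cut > m - 1L) stop("'cut' must be in 1..m-1")
  keep1 <- c1[seq_len(cut)]
  keep2 <- c2[seq_len(cut)]
  list(child1 = c(keep1, .fill_by_order(keep1, c2)),
       child2 = c(keep2, .fill_by_order(keep2, c1)))
}

#' Suffix-preserving order crossover
#'
#' Mirror of [crossover_prefix()] at the right end: each child keeps the
#' parent's positions `cut + 1 .. m` and fills the left block with the
#' missing values in the other parent's relative order.
#'
#' @inheritParams crossover_prefix
#' @return List of two integer permutations.
#' @export
crossover_suffix <- function(c1, c2, cut) {
  c1 <- .check_perm(c1, "c1"); c2 <- .check_perm(c2, "c2")
  m <- length(c1)
  if (length(c2) != m) stop("parents must have equal length")
  if (cut < 1L || cut > m - 1L) stop("'cut' must be in 1..m-1")
  keep1 <- c1[(cut + 1L):m]
  keep2 <- c2[(cut + 1L):m]
  list(child1 = c(.fill_by_order(keep1, c2), keep1),
       child2 = c(.fill_by_order(keep2, c1), keep2))
}

#' Prefix-and-suffix-preserving order crossover
#'
#' Each child keeps the parent's positions `1..cut1` and `cut2..m` and
#' fills the middle with the missing values in the other parent's relative
#' order.
#'
#' @inheritParams crossover_prefix
#' @param cut1,cut2 Cut points with `1 <= cut1 < cut2 <= m`.
#' @return List of two integer permutations.
#' @export
crossover_both <- function(c1, c2, cut1, cut2) {
  c1 <- .check_perm(c1, "c1"); c2 <- .check_perm(c2, "c2")
  m <- length(c1)
  if (length(c2) != m) stop("parents must have equal length")
  if (cut1 < 1L || cut2 <= cut1 || cut2 > m)
    stop("cut points must satisfy 1 <= cut1 < cut2 <= m")
  pre1 <- c1[seq_len(cut1)]; suf1 <- c1[cut2:m]
  pre2 <- c2[seq_len(cut1)]; suf2 <- c2[cut2:m]
  list(child1 = c(pre1, .fill_by_order(c(pre1, suf1), c2), suf1),
       child2 = c(pre2, .fill_by_order(c(pre2, suf2), c1), suf2))
}

#' Swap mutation
#'
#' Swaps the values at two distinct positions of a permutation chromosome.
#' The positions are drawn uniformly at random unless supplied.
#'
#' @param perm Integer permutation of 1..m, m >= 2.
#' @param positions Optional integer vector of two distinct positions; if
#'   `NULL`, drawn from the current RNG stream.
#' @return Integer permutation differing from `perm` in exactly the two
#'   swapped positions.
#' @examples
#' mutate_swap(c(7,3,2,9,1,5,8,6,4), positions = c(2, 6))
#' @export
mutate_swap <- function(perm, positions = NULL) {
  perm <- .check_perm(perm)
  m <- length(perm)
  if (m < 2L) stop("swap mutation needs a chromosome of length >= 2")
  if (is.null(positions)) positions <- sample.int(m, 2L)
  if (length(positions) != 2L || positions[1] == positions[2] ||
      any(positions < 1L) || any(positions > m))
    stop("'positions' must be two distinct positions in 1..m")
  perm[rev(positions)] <- perm[positions]
  perm
}
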