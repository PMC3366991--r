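# Independent brute-force oracles used to pin expected values. These
# deliberately re-derive everything from first principles (annotation,
# order vectors, exhaustive enumeration) without touching the package's
# computation paths.

# rank distance straight from the definition: annotate both strings,
# build the order vector over the union of annotated symbols (order
# n + 1 - position in a string of length n, 0 if absent), take the L1
# distance
oracle_rank_distance <- function(x, y) {
  ann <- function(s) {
    cs <- strsplit(s, "", fixed = TRUE)[[1]]
    occ <- stats::ave(seq_along(cs), cs, FUN = seq_along)
    stats::setNames(length(cs) + 1L - seq_along(cs), paste0(cs, occ))
  }
  ox <- ann(x); oy <- ann(y)
  keys <- union(names(ox), names(oy))
  vx <- ifelse(keys %in% names(ox), ox[keys], 0)
  vy <- ifelse(keys %in% names(oy), oy[keys], 0)
  sum(abs(vx - vy))
}

# Levenshtein by the textbook full-matrix recurrence
oracle_levenshtein <- function(x, y) {
  a <- strsplit(x, "", fixed = TRUE)[[1]]
  b <- strsplit(y, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n; D[1L, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    D[i + 1L, j + 1L] <- min(D[i, j] + (a[i] != b[j]),
                             D[i, j + 1L] + 1L, D[i + 1L, j] + 1L)
  D[n + 1L, m + 1L]
}

# "keep a block, fill the rest in the other parent's relative order",
# re-implemented positionally for the crossover brute-force checks
oracle_keep_fill <- function(keeper, other, keep_pos) {
  m <- length(keeper)
  child <- integer(m)
  child[keep_pos] <- keeper[keep_pos]
  child[setdiff(seq_len(m), keep_pos)] <- setdiff(other, keeper[keep_pos])
  # setdiff preserves 'other' order for distinct values
  child
}

# exhaustive closest-substring objective: double loop over inputs and all
# windows, any metric function
oracle_cssp_fitness <- function(candidate, inputs, dist_fn) {
  L <- nchar(candidate)
  max(vapply(inputs, function(x) {
    offs <- seq_len(nchar(x) - L + 1L)
    min(vapply(offs, function(o)
      dist_fn(candidate, substr(x, o, o + L - 1L)), numeric(1)))
  }, numeric(1)))
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (i in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  out
}

random_string <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
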