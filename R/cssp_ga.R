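# Genetic algorithm for the closest substring problem: fixed-length string
# chromosomes, one-point crossover, point mutation, half-normal selection,
# and windowed fitness with memoisation.

#' Enumerate the fixed-length windows of a string
#'
#' @param x Input string.
#' @param L Window length, `L <= nchar(x)`.
#' @return Data frame with columns `offset` (1-based start) and `window`;
#'   an input of length n yields exactly `n - L + 1` rows, in order.
#' @examples
#' enumerate_windows("ACGT", 2)
#' @export
enumerate_windows <- function(x, L) {
  .check_string(x, "x")
  n <- nchar(x)
  if (L < 1L || L > n)
    stop("window length must satisfy 1 <= L <= nchar(x)", call. = FALSE)
  offset <- seq_len(n - L + 1L)
  data.frame(offset = offset,
             window = substring(x, offset, offset + L - 1L),
             stringsAsFactors = FALSE)
}

#' Closest-substring fitness of a candidate
#'
#' The objective of the closest substring problem: the maximum, over the
#' input strings, of the candidate's minimum distance to any contiguous
#' window of that input. Windows have exactly the candidate's length for
#' every metric, including Levenshtein.
#'
#' @param candidate String of length L over `alphabet`.
#' @param inputs Character vector of input strings, each of length >= L.
#' @param metric One of `"rank"`, `"hamming"`, `"levenshtein"`.
#' @param alphabet Allowed letters; defaults to [dna_alphabet()].
#' @param cache Optional environment memoising results by candidate string;
#'   a cached value always equals fresh recomputation.
#' @return Non-negative number.
#' @examples
#' cssp_fitness("AC", c("ACGT", "TACG"), metric = "hamming")  # 0
#' @export
cssp_fitness <- function(candidate, inputs, metric = "rank",
                         alphabet = dna_alphabet(), cache = NULL) {
  metric <- .check_metric(metric)
  if (length(inputs) == 0L) stop("'inputs' must be non-empty")
  if (!is.null(cache)) {
    hit <- cache[[candidate]]
    if (!is.null(hit)) return(hit)
  }
  codes <- .string_codes(candidate, alphabet)
  input_codes <- lapply(as.character(inputs), .string_codes,
                        alphabet = alphabet)
  val <- .cssp_fitness_codes(codes, input_codes, metric, length(alphabet))
  if (!is.null(cache)) assign(candidate, val, envir = cache)
  val
}

.metric_code <- function(metric) {
  match(metric, c("rank", "hamming", "levenshtein")) - 1L
}

.cssp_fitness_codes <- function(codes, input_codes, metric, k) {
  mc <- .metric_code(metric)
  max(vapply(input_codes,
             function(ic) .cpp_min_window_distance(codes, ic, mc, k),
             numeric(1)))
}

#' One-point crossover of string chromosomes
#'
#' The prefixes of the two chromosomes stay in place and the suffixes are
#' interchanged; the children replace the parents unconditionally.
#'
#' @param c1,c2 Strings of equal length L.
#' @param cut Cut point, `1 <= cut <= L - 1`; if `NULL`, drawn uniformly
#'   from the current RNG stream.
#' @return List of two strings `child1`, `child2`.
#' @examples
#' one_point_crossover("AAAA", "TTTT", cut = 2)
#' @export
one_point_crossover <- function(c1, c2, cut = NULL) {
  .check_string(c1, "c1"); .check_string(c2, "c2")
  L <- nchar(c1)
  if (nchar(c2) != L) stop("parents must have equal length")
  if (L < 2L) stop("crossover needs chromosomes of length >= 2")
  if (is.null(cut)) cut <- sample.int(L - 1L, 1L)
  if (cut < 1L || cut > L - 1L) stop("'cut' must be in 1..L-1")
  list(child1 = paste0(substr(c1, 1L, cut), substr(c2, cut + 1L, L)),
       child2 = paste0(substr(c2, 1L, cut), substr(c1, cut + 1L, L)))
}

#' Point mutation of a string chromosome
#'
#' Replaces the character at one random position with a character drawn
#' uniformly from the alphabet minus the current character, so the mutant
#' always differs from the input in exactly one position.
#'
#' @param s String chromosome.
#' @param alphabet Allowed letters (size >= 2); defaults to
#'   [dna_alphabet()].
#' @param position Optional 1-based position; if `NULL`, drawn uniformly.
#' @return Mutated string.
#' @export
point_mutation <- function(s, alphabet = dna_alphabet(), position = NULL) {
  .check_string(s)
  L <- nchar(s)
  if (length(alphabet) < 2L) stop("alphabet must have at least 2 letters")
  if (is.null(position)) position <- sample.int(L, 1L)
  if (position < 1L || position > L) stop("'position' out of range")
  current <- substr(s, position, position)
  choices <- setdiff(alphabet, current)
  replacement <- choices[sample.int(length(choices), 1L)]
  substr(s, position, position) <- replacement
  s
}

#' Closest substring search by genetic algorithm
#'
#' Approximates the closest substring problem: find a length-L string
#' minimising the maximum, over the inputs, of its minimum distance to any
#' length-L window of that input. Chromosomes are nucleotide strings of
#' fixed length L, evolved with one-point crossover (children replace the
#' parents), point mutation and the same half-normal rank selection as the
#' closest string search. Window distances are memoised per candidate.
#'
#' @param inputs Character vector of at least two strings, each at least L
#'   characters long (lengths need not be equal); uppercased before any
#'   distance computation.
#' @param L Substring (chromosome) length.
#' @param config A [ga_config()].
#' @param alphabet Allowed letters; defaults to [dna_alphabet()].
#' @param use_cache Memoise fitness values (default `TRUE`; disabling it
#'   never changes any output for a fixed seed).
#' @return A `"ga_result"` with the best length-L candidate ever observed,
#'   its achieved maximum distance, and the per-generation trace.
#' @examples
#' cfg <- ga_config(40, 25, metric = "rank", seed = 1)
#' run_cssp_ga(c("ACGTACGTACGT", "TTACGTACGTAA"), L = 6, cfg)
#' @export
run_cssp_ga <- function(inputs, L, config, alphabet = dna_alphabet(),
                        use_cache = TRUE) {
  inputs <- toupper(as.character(inputs))
  if (length(inputs) < 2L)
    stop("the closest substring search needs at least two input strings")
  L <- as.integer(L)
  if (L < 2L) stop("substring length must be >= 2")
  if (L > min(nchar(inputs)))
    stop("substring length exceeds the shortest input", call. = FALSE)
  input_codes <- lapply(inputs, .string_codes, alphabet = alphabet)
  k <- length(alphabet)
  metric <- config$metric
  if (!is.null(config$seed)) set.seed(config$seed)

  ops <- list(
    evaluate = function(s)
      .cssp_fitness_codes(.string_codes(s, alphabet), input_codes,
                          metric, k),
    key = identity,
    recombine = function(c1, c2, fitness) one_point_crossover(c1, c2),
    mutate = function(s) point_mutation(s, alphabet),
    length = L
  )

  population <- replicate(
    config$population_size,
    paste(alphabet[sample.int(k, L, replace = TRUE)], collapse = ""),
    simplify = FALSE)

  out <- .ga_loop(population, config, ops, use_cache)
  .new_ga_result("closest-substring", out$best_chrom, out$best_fit,
                 out$trace, config, inputs)
}
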