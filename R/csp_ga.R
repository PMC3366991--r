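# Genetic algorithm for the closest string problem: permutation-of-ranks
# chromosomes under a fixed letter composition, three order-based
# crossovers, swap mutation, and half-normal rank selection.

#' Genetic algorithm configuration
#'
#' @param population_size Number of chromosomes per generation (>= 2).
#' @param generations Number of generations to evolve (>= 1).
#' @param crossover_prob Fraction of the population entering crossover per
#'   generation; `floor(crossover_prob * population_size)` chromosomes are
#'   drawn without replacement and paired consecutively.
#' @param mutation_prob Per-position mutation probability: each chromosome
#'   receives `Binomial(length, mutation_prob)` mutation events per
#'   generation, so the expected number of mutations per chromosome is
#'   `mutation_prob * length` and multiple mutations of one chromosome are
#'   possible but rare at the usual settings.
#' @param selection_stddev Standard deviation of the half-normal density
#'   over the best-first sorted index scale (fraction of the list);
#'   smaller values concentrate selection on the best candidates.
#' @param metric Distance used by the fitness: `"rank"`, `"hamming"` or
#'   `"levenshtein"`.
#' @param seed Optional integer seed; if non-`NULL` the run seeds R's RNG
#'   and is fully reproducible.
#' @return An object of class `"ga_config"`.
#' @export
ga_config <- function(population_size, generations,
                      crossover_prob = 0.36, mutation_prob = 0.02,
                      selection_stddev = 0.3, metric = "rank",
                      seed = NULL) {
  stopifnot(population_size >= 2, generations >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            selection_stddev >= 0)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 selection_stddev = selection_stddev,
                 metric = .check_metric(metric),
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "ga_config")
}

#' @export
print.ga_config <- function(x, ...) {
  cat(sprintf(
    "<ga_config> P=%d G=%d p_c=%g p_m=%g sel_sd=%g metric=%s seed=%s\n",
    x$population_size, x$generations, x$crossover_prob, x$mutation_prob,
    x$selection_stddev, x$metric,
    if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

# Draw n selection indices on 1..P from the half-normal index law:
# |N(0, sd^2)| truncated to [0, 1) (values >= 1 are redrawn), scaled by P
# and floored. Index 1 is the best-ranked candidate.
.half_normal_indices <- function(n, sd, P) {
  if (sd == 0) return(rep(1L, n))
  u <- abs(rnorm(n, 0, sd))
  while (any(bad <- u >= 1)) u[bad] <- abs(rnorm(sum(bad), 0, sd))
  as.integer(floor(u * P)) + 1L
}

#' Half-normal selection of the next generation
#'
#' Sorts the candidates best-first (smallest maximum distance first, stable
#' sort) and draws `population_size` indices independently from a
#' half-normal density over the sorted index scale, so the best candidates
#' are selected most often, possibly several times, while the worst may
#' never be selected.
#'
#' @param population List of chromosomes.
#' @param fitnesses Numeric vector of the candidates' maximum distances,
#'   aligned with `population`.
#' @param config A [ga_config()]; uses `population_size` and
#'   `selection_stddev`.
#' @return List of `population_size` selected chromosomes (a multiset).
#' @export
select_next_generation <- function(population, fitnesses, config) {
  stopifnot(length(population) == length(fitnesses))
  ord <- order(fitnesses, method = "radix")  # stable, best first
  idx <- .half_normal_indices(config$population_size,
                              config$selection_stddev,
                              length(population))
  population[ord[idx]]
}

#' Recombine a pair of permutation chromosomes
#'
#' Applies all three order-based crossovers -- prefix, suffix (sharing one
#' fresh cut) and prefix+suffix (a fresh ordered cut pair) -- collects the
#' six children, evaluates each child's fitness and returns the two fittest.
#' Ties are broken by generation order: prefix children first, then suffix,
#' then both-ends, first of each pair before the second.
#'
#' @param c1,c2 Integer permutations of equal length m >= 2.
#' @param fitness Function taking a chromosome and returning its maximum
#'   distance to the input set (smaller is better).
#' @return List of two chromosomes replacing the parents.
#' @export
recombine_pair <- function(c1, c2, fitness) {
  m <- length(c1)
  cut <- sample.int(m - 1L, 1L)
  cuts <- sort(sample.int(m, 2L))
  kids <- c(crossover_prefix(c1, c2, cut),
            crossover_suffix(c1, c2, cut),
            crossover_both(c1, c2, cuts[1], cuts[2]))
  f <- vapply(kids, fitness, numeric(1))
  kids[order(f, method = "radix")[1:2]]
}

# shared GA driver: the closest-string and closest-substring searches differ
# only in their operators, bundled as a list of closures
.ga_loop <- function(population, config, ops, use_cache) {
  P <- config$population_size
  G <- config$generations
  cache <- if (use_cache) new.env(hash = TRUE, parent = emptyenv())
  fitness <- function(chrom) {
    if (is.null(cache)) return(ops$evaluate(chrom))
    key <- ops$key(chrom)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- ops$evaluate(chrom)
    assign(key, val, envir = cache)
    val
  }

  fit <- vapply(population, fitness, numeric(1))
  best_i <- which.min(fit)
  best_chrom <- population[[best_i]]
  best_fit <- fit[best_i]

  trace <- data.frame(generation = seq_len(G),
                      gen_best = NA_real_, best_so_far = NA_real_)
  n_cross <- floor(config$crossover_prob * P)

  for (g in seq_len(G)) {
    if (n_cross >= 2L) {
      who <- sample.int(P, n_cross)
      for (j in seq_len(n_cross %/% 2L)) {
        i1 <- who[2L * j - 1L]; i2 <- who[2L * j]
        pair <- ops$recombine(population[[i1]], population[[i2]], fitness)
        population[[i1]] <- pair[[1]]
        population[[i2]] <- pair[[2]]
      }
    }
    for (i in seq_len(P)) {
      n_mut <- stats::rbinom(1L, ops$length, config$mutation_prob)
      for (t in seq_len(n_mut))
        population[[i]] <- ops$mutate(population[[i]])
    }
    fit <- vapply(population, fitness, numeric(1))
    g_i <- which.min(fit)
    if (fit[g_i] < best_fit) {
      best_fit <- fit[g_i]
      best_chrom <- population[[g_i]]
    }
    trace$gen_best[g] <- fit[g_i]
    trace$best_so_far[g] <- best_fit
    population <- select_next_generation(population, fit, config)
  }

  list(best_chrom = best_chrom, best_fit = best_fit, trace = trace)
}

.new_ga_result <- function(problem, best, distance, trace, config, inputs) {
  structure(list(problem = problem, best = best, distance = distance,
                 trace = trace, config = config, inputs = inputs),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result: %s, metric=%s>\n", x$problem, x$config$metric))
  cat(sprintf("  distance achieved: %g\n", x$distance))
  cat(sprintf("  best candidate:    %s\n", x$best))
  cat(sprintf("  generations:       %d\n", nrow(x$trace)))
  invisible(x)
}

#' Closest string search by genetic algorithm
#'
#' Approximates the closest string problem: find a string minimising the
#' maximum distance (the radius) to every input string. Candidates are
#' permutations of annotated-symbol ranks under the letter composition of
#' the first input, evolved with the three order-based crossovers (the two
#' fittest of the six children replace the parents), swap mutation and
#' half-normal rank selection. Fitness values are memoised per chromosome.
#'
#' @param inputs Character vector of at least two equal-length strings;
#'   uppercased before any distance computation.
#' @param config A [ga_config()].
#' @param alphabet Allowed letters; defaults to [dna_alphabet()].
#' @param init_candidates Optional character vector of strings (with the
#'   first input's composition) injected into generation 0, e.g. to seed
#'   the search with a known candidate.
#' @param use_cache Memoise fitness values by chromosome (default `TRUE`;
#'   disabling it never changes any output for a fixed seed).
#' @return A `"ga_result"`: the best decoded string ever observed, its
#'   maximum distance to the inputs, and a per-generation trace
#'   (`generation`, `gen_best`, `best_so_far`; the best-so-far column is
#'   non-increasing).
#' @examples
#' cfg <- ga_config(30, 20, metric = "rank", seed = 1)
#' run_csp_ga(c("ACGTACGT", "ACGTTGCA"), cfg)
#' @export
run_csp_ga <- function(inputs, config, alphabet = dna_alphabet(),
                       init_candidates = NULL, use_cache = TRUE) {
  inputs <- toupper(as.character(inputs))
  if (length(inputs) < 2L)
    stop("the closest string search needs at least two input strings")
  if (length(unique(nchar(inputs))) != 1L)
    stop("all input strings must have equal length", call. = FALSE)
  input_codes <- lapply(inputs, .string_codes, alphabet = alphabet)
  k <- length(alphabet)
  metric <- config$metric
  map <- composition_map(inputs[[1]])
  m <- map$size
  if (m < 2L) stop("input strings must have length >= 2")
  if (!is.null(config$seed)) set.seed(config$seed)

  evaluate <- function(perm) {
    codes <- .string_codes(decode_string(perm, map), alphabet)
    max(vapply(input_codes, function(ic) {
      switch(metric,
             rank        = .cpp_rank_distance(codes, ic, k),
             hamming     = .cpp_hamming(codes, ic),
             levenshtein = .cpp_levenshtein(codes, ic))
    }, numeric(1)))
  }
  ops <- list(
    evaluate = evaluate,
    key = function(perm) paste(perm, collapse = " "),
    recombine = recombine_pair,
    mutate = mutate_swap,
    length = m
  )

  population <- replicate(config$population_size, sample.int(m),
                          simplify = FALSE)
  if (!is.null(init_candidates)) {
    seeds <- lapply(toupper(init_candidates), encode_string, map = map)
    population[seq_along(seeds)] <- seeds
  }

  out <- .ga_loop(population, config, ops, use_cache)
  .new_ga_result("closest-string", decode_string(out$best_chrom, map),
                 out$best_fit, out$trace, config, inputs)
}
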