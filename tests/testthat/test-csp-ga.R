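test_that("recombination keeps the two fittest of the six children", {
  set.seed(51)
  inputs <- c("ACGTGACA", "GTCAACGT")
  map <- composition_map(inputs[1])
  fitness <- function(perm)
    max_distance_to_set(decode_string(perm, map), inputs, "rank")
  for (i in 1:20) {
    c1 <- sample.int(8); c2 <- sample.int(8)
    seed <- sample.int(1e6, 1)
    set.seed(seed)
    pair <- recombine_pair(c1, c2, fitness)
    # replay the draws to rebuild the six children independently
    set.seed(seed)
    cut <- sample.int(7, 1); cuts <- sort(sample.int(8, 2))
    kids <- c(crossover_prefix(c1, c2, cut),
              crossover_suffix(c1, c2, cut),
              crossover_both(c1, c2, cuts[1], cuts[2]))
    f <- vapply(kids, fitness, numeric(1))
    expect_setequal(vapply(pair, fitness, numeric(1)),
                    unname(sort(f)[1:2]))
    for (child in pair) expect_identical(sort(child), 1:8)
  }
  # identical parents: all six children equal the parent
  p <- sample.int(8)
  pair <- recombine_pair(p, p, fitness)
  expect_identical(pair[[1]], p)
  expect_identical(pair[[2]], p)
})

test_that("half-normal selection favours the best-ranked candidates", {
  pop <- as.list(1:20)          # candidate i has fitness i: already sorted
  fit <- as.numeric(1:20)
  cfg <- ga_config(20, 1, selection_stddev = 0.2)
  set.seed(61)
  draws <- unlist(replicate(500, select_next_generation(pop, fit, cfg)))
  expect_length(draws, 20 * 500)
  counts <- tabulate(draws, nbins = 20)
  # selection frequency non-increasing in rank (allowing sampling noise on
  # neighbours by comparing with a lag of 3)
  expect_true(all(diff(counts, lag = 3) <= 0))
  # degenerate density: everything collapses onto the best candidate
  cfg0 <- ga_config(20, 1, selection_stddev = 0)
  expect_true(all(unlist(select_next_generation(pop, fit, cfg0)) == 1L))
})

test_that("selection sorts stably and conserves population size", {
  pop <- as.list(letters[1:6])
  fit <- c(3, 1, 2, 1, 5, 2)
  cfg <- ga_config(6, 1, selection_stddev = 0)
  # all draws hit rank 1; stable sort makes that the first fitness-1 entry
  out <- select_next_generation(pop, fit, cfg)
  expect_length(out, 6)
  expect_true(all(unlist(out) == "b"))
})

test_that("the closest string search finds the optimum of identical inputs", {
  x <- "ACGGTTCA"
  cfg <- ga_config(20, 10, metric = "rank", seed = 2)
  res <- run_csp_ga(c(x, x), cfg, init_candidates = x)
  expect_equal(res$distance, 0)
  expect_identical(res$best, x)
})

test_that("closest string traces are monotone and runs deterministic", {
  inputs <- c("ACGTACGTAC", "GTGTACATCA")
  for (metric in c("rank", "hamming", "levenshtein")) {
    cfg <- ga_config(24, 15, metric = metric, seed = 9)
    r1 <- run_csp_ga(inputs, cfg)
    r2 <- run_csp_ga(inputs, cfg)
    expect_identical(r1$trace, r2$trace)
    expect_identical(r1$best, r2$best)
    expect_true(all(diff(r1$trace$best_so_far) <= 0))
    expect_true(all(r1$trace$gen_best >= r1$trace$best_so_far))
    # decoded best conserves the first input's composition
    expect_identical(sort(strsplit(r1$best, "")[[1]]),
                     sort(strsplit(inputs[1], "")[[1]]))
  }
})

test_that("fitness memoisation never changes a seeded run", {
  inputs <- c("ACGTACGT", "TTGACCGA")
  cfg <- ga_config(16, 12, metric = "rank", seed = 4)
  with_cache <- run_csp_ga(inputs, cfg, use_cache = TRUE)
  without <- run_csp_ga(inputs, cfg, use_cache = FALSE)
  expect_identical(with_cache$trace, without$trace)
  expect_identical(with_cache$best, without$best)
})

test_that("the search at least matches a random-candidate baseline", {
  set.seed(71)
  inputs <- c(random_string(8), random_string(8))
  cfg <- ga_config(30, 50, metric = "rank", seed = 5)
  ga <- run_csp_ga(inputs, cfg)
  map <- composition_map(inputs[1])
  set.seed(99)
  baseline <- min(vapply(1:500, function(i)
    max_distance_to_set(decode_string(sample.int(8), map), inputs, "rank"),
    numeric(1)))
  expect_lte(ga$distance, baseline)
})

test_that("invalid closest string inputs are rejected early", {
  cfg <- ga_config(10, 5)
  expect_error(run_csp_ga("ACGT", cfg), "at least two")
  expect_error(run_csp_ga(c("ACGT", "ACG"), cfg), "equal length")
})
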