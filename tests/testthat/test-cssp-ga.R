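test_that("window enumeration lists every offset in order", {
  w <- enumerate_windows("ACGT", 4)
  expect_equal(nrow(w), 1L)
  expect_identical(w$window, "ACGT")
  w <- enumerate_windows("ACGT", 2)
  expect_identical(w$window, c("AC", "CG", "GT"))
  expect_identical(w$offset, 1:3)
  expect_error(enumerate_windows("ACG", 4), "window length")
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:15, 1); L <- sample(1:n, 1)
    expect_equal(nrow(enumerate_windows(random_string(n), L)), n - L + 1)
  }
})

test_that("the windowed fitness equals an exhaustive double loop", {
  expect_equal(cssp_fitness("AC", c("ACGT", "TACG"), "hamming"), 0)
  set.seed(37)
  dist_fns <- list(rank = rank_distance,
                   hamming = hamming_distance,
                   levenshtein = levenshtein_distance)
  for (i in 1:30) {
    L <- sample(2:4, 1)
    inputs <- replicate(sample(2:3, 1), random_string(sample(L:8, 1) + 4))
    cand <- random_string(L)
    for (metric in names(dist_fns))
      expect_equal(cssp_fitness(cand, inputs, metric),
                   oracle_cssp_fitness(cand, inputs, dist_fns[[metric]]))
  }
})

test_that("a window shared by every input has fitness zero", {
  set.seed(43)
  inst <- plant_common_substring(3, 40, 6, seed = 77)
  for (metric in c("rank", "hamming", "levenshtein"))
    expect_equal(cssp_fitness(inst$planted, inst$inputs, metric), 0)
})

test_that("a cached fitness value equals fresh recomputation", {
  cache <- new.env(parent = emptyenv())
  inputs <- c("ACGTACGTA", "TTACGGACT")
  set.seed(53)
  for (i in 1:20) {
    cand <- random_string(3)
    v1 <- cssp_fitness(cand, inputs, "rank", cache = cache)
    v2 <- cssp_fitness(cand, inputs, "rank", cache = cache)  # cache hit
    v3 <- cssp_fitness(cand, inputs, "rank")                 # no cache
    expect_equal(v1, v2)
    expect_equal(v1, v3)
  }
})

test_that("one-point crossover swaps suffixes and conserves columns", {
  kids <- one_point_crossover("AAAA", "TTTT", cut = 2)
  expect_identical(kids$child1, "AATT")
  expect_identical(kids$child2, "TTAA")
  p <- "ACGTGA"
  kids <- one_point_crossover(p, p, cut = 3)
  expect_identical(kids$child1, p)
  set.seed(47)
  for (i in 1:25) {
    L <- sample(2:10, 1)
    c1 <- random_string(L); c2 <- random_string(L)
    cut <- sample.int(L - 1, 1)
    kids <- one_point_crossover(c1, c2, cut)
    for (j in seq_len(L)) {
      parents <- sort(c(substr(c1, j, j), substr(c2, j, j)))
      children <- sort(c(substr(kids$child1, j, j),
                         substr(kids$child2, j, j)))
      expect_identical(children, parents)
    }
  }
  expect_error(one_point_crossover("AAAA", "TTTT", cut = 4), "cut")
})

test_that("point mutation changes exactly one position, never to itself", {
  set.seed(59)
  for (i in 1:50) {
    s <- random_string(sample(1:10, 1))
    m <- point_mutation(s)
    expect_equal(hamming_distance(s, m), 1)
  }
  for (i in 1:20) expect_false(point_mutation("AAAA") == "AAAA")
  # replacement uniform over the three other letters
  draws <- vapply(1:6000, function(i) point_mutation("A"), "")
  freq <- table(draws) / 6000
  expect_setequal(names(freq), c("C", "G", "T"))
  expect_true(all(abs(freq - 1 / 3) < 0.03))
})

test_that("the substring search recovers planted optima on small instances", {
  # a shared block longer than the search length gives several optimal
  # windows, as in conserved stretches of related sequences
  for (s in 1:3) {
    inst <- plant_common_substring(2, 60, 20, seed = 100 + s)
    res <- run_cssp_ga(inst$inputs, 8,
                       ga_config(150, 80, metric = "rank", seed = s))
    expect_equal(res$distance, 0)
    expect_equal(cssp_fitness(res$best, inst$inputs, "rank"), 0)
  }
})

test_that("substring search traces are monotone, deterministic, cache-blind", {
  inputs <- c("ACGTTGCAACGGTA", "GGTACGTTAACCGT")
  for (metric in c("rank", "hamming", "levenshtein")) {
    cfg <- ga_config(20, 15, metric = metric, seed = 8)
    r1 <- run_cssp_ga(inputs, 5, cfg)
    r2 <- run_cssp_ga(inputs, 5, cfg)
    r3 <- run_cssp_ga(inputs, 5, cfg, use_cache = FALSE)
    expect_identical(r1$trace, r2$trace)
    expect_identical(r1$trace, r3$trace)
    expect_identical(r1$best, r3$best)
    expect_true(all(diff(r1$trace$best_so_far) <= 0))
    expect_equal(nchar(r1$best), 5L)
  }
})

test_that("substring search validates its inputs", {
  cfg <- ga_config(10, 5)
  expect_error(run_cssp_ga("ACGT", 2, cfg), "at least two")
  expect_error(run_cssp_ga(c("ACGT", "ACG"), 4, cfg), "shortest input")
})
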