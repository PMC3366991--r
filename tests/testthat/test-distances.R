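test_that("annotation tags occurrences in order and preserves letters", {
  a <- annotate("alibaba")
  expect_identical(a$letter, c("a", "l", "i", "b", "a", "b", "a"))
  expect_identical(a$occ, c(1L, 1L, 1L, 1L, 2L, 2L, 3L))
  expect_identical(annotate("A")$occ, 1L)
  expect_identical(annotate("AAC")$letter, c("A", "A", "C"))
  expect_identical(annotate("AAC")$occ, c(1L, 2L, 1L))
  expect_error(annotate(""), "empty")
  # per-letter occurrence indices always run 1..count(letter)
  set.seed(11)
  for (i in 1:20) {
    s <- random_string(sample(1:12, 1))
    a <- annotate(s)
    for (l in unique(a$letter))
      expect_identical(a$occ[a$letter == l], seq_len(sum(a$letter == l)))
  }
})

test_that("rankings require distinct items and print positions in order", {
  expect_error(ranking(c("a", "a")), "distinct")
  expect_error(ranking(character(0)), "at least one")
  r <- as_ranking(annotate("AAC"))
  expect_identical(as.character(r), c("A.1", "A.2", "C.1"))
})

test_that("rank distance on rankings matches the definitional oracle", {
  expect_equal(rank_distance_rankings(ranking(letters[1:3]),
                                      ranking(letters[1:3])), 0)
  # full rankings of the same universe: Spearman footrule
  expect_equal(rank_distance_rankings(ranking(c("a", "b", "c")),
                                      ranking(c("c", "b", "a"))), 4)
  # partial overlap: shared 'a' contributes 0, each unshared item its order
  expect_equal(rank_distance_rankings(ranking(c("a", "b")),
                                      ranking(c("a", "c"))), 2)
  # string-level distance agrees with the independent oracle
  set.seed(7)
  for (i in 1:50) {
    x <- random_string(sample(1:10, 1))
    y <- random_string(sample(1:10, 1))
    expect_equal(rank_distance(x, y), oracle_rank_distance(x, y))
  }
})

test_that("rank distance between strings matches hand-checked values", {
  expect_equal(rank_distance("ACGT", "ACGT"), 0)
  # equal length, all symbols paired: sum of position gaps
  expect_equal(rank_distance("AACG", "ACGA"), 4)
  # composition mismatch: unpaired symbols contribute their orders
  expect_equal(rank_distance("AA", "AC"), 2)
  expect_equal(rank_distance("AA", "AC"), oracle_rank_distance("AA", "AC"))
})

test_that("linear-time rank distance equals the definitional path", {
  expect_equal(rank_distance_linear("AACG", "ACGA"), 4)
  expect_equal(rank_distance_linear("T", "T"), 0)
  # exhaustive: all pairs of strings of length 1..4 over a 2-letter alphabet
  strs <- unlist(lapply(1:4, function(n) {
    apply(expand.grid(rep(list(c("A", "C")), n)), 1, paste, collapse = "")
  }))
  for (x in strs) for (y in strs)
    expect_equal(rank_distance_linear(x, y, c("A", "C")),
                 rank_distance(x, y))
  # randomized: longer strings over the DNA alphabet, unequal lengths too
  set.seed(21)
  for (i in 1:300) {
    x <- random_string(sample(1:12, 1))
    y <- random_string(sample(1:12, 1))
    expect_equal(rank_distance_linear(x, y), rank_distance(x, y))
  }
})

test_that("characters outside the declared alphabet are a named error", {
  expect_error(rank_distance_linear("ACGX", "ACGT", dna_alphabet()),
               "'X' at position 4")
  expect_error(max_distance_to_set("ACNT", "ACGT", "rank", dna_alphabet()),
               "position 3")
})

test_that("rank distance satisfies the metric axioms", {
  set.seed(33)
  trips <- replicate(60, random_string(sample(1:10, 1)))
  for (i in seq(1, 58, by = 3)) {
    x <- trips[i]; y <- trips[i + 1]; z <- trips[i + 2]
    dxy <- rank_distance_linear(x, y)
    expect_gte(dxy, 0)
    expect_equal(dxy, rank_distance_linear(y, x))
    expect_equal(rank_distance_linear(x, x), 0)
    if (x != y) expect_gt(dxy, 0)
    expect_lte(rank_distance_linear(x, z),
               dxy + rank_distance_linear(y, z))
  }
})

test_that("rank distance reduces to the Spearman footrule on permutations", {
  set.seed(5)
  syms <- c("A", "C", "G", "T", "B", "D")
  for (i in 1:25) {
    n <- sample(2:6, 1)
    p1 <- sample(syms, n); p2 <- sample(p1)
    foot <- sum(abs(match(p1, p1) - match(p1, p2)))
    expect_equal(rank_distance(paste(p1, collapse = ""),
                               paste(p2, collapse = "")), foot)
  }
})

test_that("rank distance of equal-length strings is at most m(m+1)", {
  set.seed(13)
  for (i in 1:40) {
    m <- sample(1:12, 1)
    expect_lte(rank_distance_linear(random_string(m), random_string(m)),
               m * (m + 1))
  }
})

test_that("hamming distance counts mismatches and rejects unequal lengths", {
  expect_equal(hamming_distance("ACGT", "ACGT"), 0)
  expect_equal(hamming_distance("AAAA", "TTTT"), 4)
  expect_equal(hamming_distance("ACGT", "AGGA"), 2)
  expect_error(hamming_distance("AC", "ACG"), "equal-length")
})

test_that("levenshtein distance matches the DP oracle and adist", {
  expect_equal(levenshtein_distance("ACGT", "ACGT"), 0)
  expect_equal(levenshtein_distance("A", ""), 1)
  expect_equal(levenshtein_distance("kitten", "sitting"), 3)
  set.seed(17)
  for (i in 1:40) {
    x <- random_string(sample(0:9, 1) + 1)
    y <- random_string(sample(0:9, 1))
    y <- if (nchar(y) == 0) "" else y
    expect_equal(levenshtein_distance(x, y), oracle_levenshtein(x, y))
    expect_equal(levenshtein_distance(x, y),
                 as.integer(utils::adist(x, y)))
  }
})

test_that("levenshtein never exceeds hamming on equal-length strings", {
  set.seed(29)
  for (i in 1:30) {
    m <- sample(1:10, 1)
    x <- random_string(m); y <- random_string(m)
    expect_lte(levenshtein_distance(x, y), hamming_distance(x, y))
  }
})

test_that("max distance to a set is the largest per-input distance", {
  expect_equal(max_distance_to_set("ACGT", "ACGT", "rank"), 0)
  expect_equal(max_distance_to_set("AA", c("AA", "AC"), "rank"), 2)
  expect_equal(max_distance_to_set("AC", c("AA", "CC"), "hamming"), 1)
  expect_error(max_distance_to_set("AC", character(0), "rank"), "non-empty")
})
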