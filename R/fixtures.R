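# Deterministic instance generators and embedded reference data, so every
# stage of the pipeline is testable without downloads. The generator RNG is
# local to each call (seeded independently of any GA run), so fixture
# identity never depends on GA settings.

#' Uniform random DNA string
#'
#' @param n Length (>= 1).
#' @param seed Optional integer seed; the draw uses a local RNG state, so
#'   it neither disturbs nor depends on the caller's RNG.
#' @param alphabet Letters to draw from; defaults to [dna_alphabet()].
#' @return A length-`n` string; deterministic per seed.
#' @export
random_dna <- function(n, seed = NULL, alphabet = dna_alphabet()) {
  if (n < 1L) stop("'n' must be >= 1")
  .with_local_seed(seed, {
    paste(alphabet[sample.int(length(alphabet), n, replace = TRUE)],
          collapse = "")
  })
}

# evaluate expr under an optional local seed, restoring the caller's RNG
.with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Planted common-substring instance
#'
#' Generates uniform random background strings and overwrites, in each of
#' them, one randomly placed window with the same random length-L block.
#' The planted block then occurs verbatim at the recorded offset of every
#' input, so the optimum closest-substring distance is 0 for all three
#' metrics.
#'
#' @param n_inputs Number of input strings (>= 2).
#' @param n Length of each input.
#' @param L Length of the planted block, `L <= n`.
#' @param seed Optional integer seed (local RNG, as in [random_dna()]).
#' @param alphabet Letters; defaults to [dna_alphabet()].
#' @return A list of class `"planted_instance"` with fields `inputs`
#'   (character vector), `planted` (the common block) and `offsets`
#'   (1-based start of the block in each input).
#' @export
plant_common_substring <- function(n_inputs = 2L, n, L, seed = NULL,
                                   alphabet = dna_alphabet()) {
  if (n_inputs < 2L) stop("'n_inputs' must be >= 2")
  if (L < 1L || L > n) stop("'L' must satisfy 1 <= L <= n")
  .with_local_seed(seed, {
    planted <- paste(alphabet[sample.int(length(alphabet), L,
                                         replace = TRUE)], collapse = "")
    offsets <- integer(n_inputs)
    inputs <- character(n_inputs)
    for (i in seq_len(n_inputs)) {
      bg <- paste(alphabet[sample.int(length(alphabet), n,
                                      replace = TRUE)], collapse = "")
      off <- sample.int(n - L + 1L, 1L)
      substr(bg, off, off + L - 1L) <- planted
      inputs[i] <- bg
      offsets[i] <- off
    }
    structure(list(inputs = inputs, planted = planted, offsets = offsets),
              class = "planted_instance")
  })
}

#' Published reference fixtures
#'
#' Verbatim copies (whitespace stripped) of the published worked examples
#' and benchmark results this package reproduces: the two artificial test
#' sequences with their known exact common substring, the three length-9
#' worked-example chromosomes together with the expected prefix-crossover
#' children (cut 4) and the expected swap mutants, the printed closest
#' string/substring of every desk-scale benchmark with its achieved
#' distance, and the EMBL accessions of the mitochondrial genomes used by
#' the accession-based benchmarks.
#'
#' @return A list with components:
#'   \describe{
#'     \item{artificial_pair}{two structured DNA sequences (100 and 90 nt)
#'       sharing the exact 30-nt window `T^25 G^5`.}
#'     \item{artificial_closest_substring}{that window, `T^25 G^5`.}
#'     \item{chromosomes}{list `C1`, `C2`, `C3` of length-9 permutations.}
#'     \item{recombined_prefix_cut4}{expected children of
#'       `crossover_prefix(C1, C2, 4)`.}
#'     \item{mutated}{expected results of swapping positions (2,6) of `C1`,
#'       and positions (2,6) then (5,8) of `C3`.}
#'     \item{results}{data frame of benchmark results: `test_case`, `pair`,
#'       `metric`, `problem`, `prefix_length`, `substring_length`,
#'       `distance`, `candidate` (NA where no candidate was printed).}
#'     \item{accessions}{named character vector of EMBL accessions.}
#'   }
#' @export
reference_fixtures <- function() {
  seq1 <- paste0(strrep("A", 12), strrep("T", 25), strrep("G", 5),
                 strrep("A", 27), strrep("G", 10), strrep("T", 5),
                 strrep("A", 16))
  seq2 <- paste0(strrep("C", 10), strrep("G", 10), strrep("T", 5),
                 strrep("C", 18), strrep("T", 25), strrep("G", 5),
                 strrep("C", 17))
  results <- data.frame(
    test_case = c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2,
                  3, 3, 3, 3, 3, 3, 3, 3, 3,
                  4, 4, 4, 4, 4, 4, 4, 4, 4,
                  5, 5, 5, 6, 6, 7, 7, 8, 8, 9, 9),
    pair = c("human_chimpanzee", "human_donkey", "human_chimpanzee",
             "human_donkey", "human_chimpanzee", "human_donkey",
             "human_chimpanzee", "human_donkey", "human_chimpanzee",
             "human_donkey", "human_chimpanzee", "human_donkey",
             "rat_house_mouse", "rat_fat_dormouse", "rat_cow",
             "rat_house_mouse", "rat_fat_dormouse", "rat_cow",
             "rat_house_mouse", "rat_fat_dormouse", "rat_cow",
             "rat_house_mouse", "rat_fat_dormouse", "rat_cow",
             "rat_house_mouse", "rat_fat_dormouse", "rat_cow",
             "rat_house_mouse", "rat_fat_dormouse", "rat_cow",
             "artificial", "artificial", "artificial",
             "human_chimpanzee", "human_gorilla", "human_chimpanzee",
             "human_gorilla", "human_chimpanzee", "human_gorilla",
             "human_chimpanzee", "human_gorilla"),
    metric = c("rank", "rank", "hamming", "hamming", "levenshtein",
               "levenshtein", "rank", "rank", "hamming", "hamming",
               "levenshtein", "levenshtein", "rank", "rank", "rank",
               "hamming", "hamming", "hamming", "levenshtein",
               "levenshtein", "levenshtein", "rank", "rank", "rank",
               "hamming", "hamming", "hamming", "levenshtein",
               "levenshtein", "levenshtein", "rank", "hamming",
               "levenshtein", "rank", "rank", "rank", "rank", "rank",
               "rank", "rank", "rank"),
    problem = rep(c("csp", "cssp", "csp", "cssp", "cssp", "csp"),
                  c(6, 6, 9, 9, 3, 8)),
    prefix_length = rep(c(200, 300, 150, 300, NA, 800, 5000, 7000, 16000),
                        c(6, 6, 9, 9, 3, 2, 2, 2, 2)),
    substring_length = rep(c(NA, 24, NA, 24, 30, NA),
                           c(6, 6, 9, 9, 3, 8)),
    distance = c(3698, 5001, 73, 77, 63, 59, 26, 34, 7, 7, 4, 4,
                 454, 1209, 3321, 45, 43, 56, 14, 28, 46,
                 0, 4, 22, 0, 1, 7, 1, 1, 6, 0, 0, 0,
                 43207, 45544, 426232, 358525, 682664, 656806,
                 2412780, 2089976),
    candidate = c(
      "GTACTACGCGTTTACTCTACCAAACGCATACTGACAAATGTCTGTTAGATGGATCCATCTCCGCGTGTACTGTCTAAAAGCGTAGCGTCACGTACGTCAAGCAGTGTTTCAGTCCCACAATCCATTGCACATTACTGAGCTCTCCATTCGTCTCACTCTTTTTACGAACAATATTATCAATGCAAACGTGGGCCCTCTTC",
      "TGAAGAGCATTCCATATCTAACTCCTGAAGTACACGAACGGATATGCACTTTGCTTCGTTACACTAGCGTGGACGTACATTCTCGGCTGACCTTGGGCATATAATATTAAAGTAACGGAGTCTACATCTAATATCATCGTAACCCATAGAATGTTATACCCTCATCGTCCTTCGCCCAAGTGCCCTGCTTAACTTCTCAT",
      "GATCATGTGGCTATCACCCTCAAAGCCACTCACGGGAACTGTTCAGACATTTTTACATTACCCCATGAAGATATGCGCGTGGTACTATTCTGTCAAGCAGCAGTCAGAAAACTCACTCTTGCAATAACTGTCTTTGCTTGCTTCATCATCTTAATCTCTATCATCACTAGGTACAATAATACAGGCCGACGCACTGCAGC",
      "GATCACAGAGCTAAAAGACAACAAACCACGCACCTGAAAATGCCAAGATTTTGGTTCCTACGCCTTGGGCATATACACTCGATCCCGTTCTGATACTCTGTAACCGGTGCAACCACTCATGCAAGATTCGTCATTCCTGCCTGAATGATCTCTTTATTGAACTCTCCGATCTTAAGGAGCAGGTGCGAACAAAATTACTA",
      "GTATACACAGCTCTACCCCCTAAAGCAATACCACGGAAGATCTTCCATGGATTTATATCATCCTCTAAGCAACATGCATGGTAGCCTTGCGATTCGATTGAGCTCGTGAGACCCTATATCGCATACTGATCCCCGATCCTGGTCATCCTATTAATCATCCATGTAAAGTTACAAGTATTACAGCGCGCAGCAATTACAAC",
      "GTTCAATGTACTATCACGATATAAATCAAGGAGCTGTCAATGCACTTGGTAGTTTCCTCTGCGCTATGCACACATAGGGCATTGCGACCTGGAGCCTTATTATTACTATGAAGCAGATTAACATGCATTGATTCCTGCCTCCCCATATAATCCTCTAAATCGCACTCTAGATCAAATTACAGGCGAACAAGACTCTACTA",
      "CTTAGTAACTATATCGAGACAAGC",
      "ACATGCCTATCTACCCGTAATACC",
      "CTACACACGCAAGCCTTCCCTGCA",
      "ACGTACGAACCATACTACAAGCTA",
      "TTGATTCCTGCCTATCTATTAGCT",
      "ATGCTACTCTTAATCGCACCTACG",
      "GTTGAATCGTTAATATACAAAGCAAGTACATGAATCAGAAGTGATATTCTAAAAGCTTAGCAACCATCAAATATGTGGCCGTGTTCTACATTTAAGTGAAGATGTAAATCAAACCTAAGCATCATGACATGCGAATCAAGCATACCTATT",
      "GTATACTGTAGTATAAAAAATCTGAGACCATGATAATGTACAGTAGGATACATACCTAACCGCAACAATTGATGCCGTGTACGCTTAATTTCAATGTCTCTAGCAGGAAGAAAATTTGCAAACTTCCAACGAAAGTCGCTAAATGTCCAT",
      "GTATAACATGTCACTGAACCGAATACTAGTAATGAAAATTCGGCTCTTATGCAAGACTTATACTTTCAGGAGGATCGATTTTAGAACATGAAAATGCTAGGCTGTAGTGGCGTAGATCACTAGGCAGCTGCTTGTTCTTTTGTCAACTGG",
      "GTTAATGTAGCTTATTAACAAGGAAAGGAATTGAAAATGTTTAGTGGGTTCAATATTCCCAATAACCCAAAGGGTTGGTCCCGGGCCTGTAAATAAATTAAGGGTAGAATAAACATTCAAAACCCCCAAAAACCGGGTTAAAACCCTTTA",
      "GTTAATGTAGCTTATAATAAGCAAAACCATTAAAAAGCTTTGGATGGAATCTAAAACCCCTAAAACAAAAAGTTTGGGCCCAGGCTTTTTAATTGTTTGTAGGAAAAATAAACATTGCAACAATCACGACACCGGTATAAAACCCTTTAC",
      "ATTAATGGATAATCTGCTAATGCAAAGACATGACAATGCTGTGATAGATTTAGAAATTCTATAATCAGGAAGGTTTTGGCATTCAGCTATGGTTGACTGAGGGTATGATTCGACACATAAACTTCAATAGGCCTTAGCAGAATCTTTAGA",
      "GTTAATGTAGCTTATAATAAAGCAAAGCACTGAAAAGCTTAGATGGATCAAATGATCCCATAAACACAAAGGTTTGGTCCTGGCCTAAATAATTAGAGGTAAAGATCTACACATGCAAACCTCCATAGACCGGTGTAAACATCCCGTTAA",
      "TTAATGAGCTTAAAAGCAAAGCAACTGAAATGCTTAGATGGTAGCAAATATCCCATAAACACAAAGGTTCTGGTCCCAGCCTTCTATTAATTAGATTGTATAGCAAGATTACACATGCAACATCATGAACCTGGTGTAAGAATCCCTTAA",
      "GACTAATGGCTATCAGAATGCAAAGCACATGAACATGCTGCTGAGATAGATTTGAAAATCTTTAATACTGGAAGGGTTGCTCCTGGACTCATAGCTATGGACGTAAGGCTTGACACAGCATACATTGTACCGGAGTAAAATGCACTTAAG",
      "AAAGCAAAGCACTGAAAATGCTTA",
      "ATAAGACAAGCACTGAAAATGCTT",
      "AGATACGTTCAGTACATGAGTACC",
      "TCAGCAGTGATAAATATTAAGCAA",
      "CCCCATAAACACAAAGGTTTGGTC",
      "GTAATTGGACATAAATTTTCACAT",
      "TAAAAAAGCAAAGCACTGAAAATG",
      "TAAACGAAAGTTTGACTAAGCTAG",
      "CAAACATCTACCACCCGGTTAAAA",
      "TTTTTTTTTTTTTTTTTTTTTTTTTGGGGG",
      "TTTTTTTTTTTTTTTTTTTTTTTTTGGGGG",
      "TTTTTTTTTTTTTTTTTTTTTTTTTGGGGG",
      NA, NA, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)

  list(
    artificial_pair = c(seq1, seq2),
    artificial_closest_substring = paste0(strrep("T", 25), strrep("G", 5)),
    chromosomes = list(C1 = c(7L, 3L, 2L, 9L, 1L, 5L, 8L, 6L, 4L),
                       C2 = c(4L, 8L, 1L, 6L, 3L, 7L, 9L, 5L, 2L),
                       C3 = c(2L, 5L, 9L, 8L, 7L, 1L, 3L, 4L, 6L)),
    recombined_prefix_cut4 = list(
      child1 = c(7L, 3L, 2L, 9L, 4L, 8L, 1L, 6L, 5L),
      child2 = c(4L, 8L, 1L, 6L, 7L, 3L, 2L, 9L, 5L)),
    mutated = list(C1 = c(7L, 5L, 2L, 9L, 1L, 3L, 8L, 6L, 4L),
                   C3 = c(2L, 1L, 9L, 8L, 4L, 5L, 3L, 7L, 6L)),
    results = results,
    accessions = c(human = "V00662", chimpanzee = "D38116",
                   gorilla = "D38114", donkey = "X97337",
                   rat = "X14848", house_mouse = "V00711",
                   fat_dormouse = "AJ001562", cow = "V00654")
  )
}
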