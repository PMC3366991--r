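---
title: "Closest strings and substrings by rank distance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closest strings and substrings by rank distance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdclosest)
```

## The problems

Given a set of strings over a finite alphabet, the *closest string
problem* (CSP) asks for a string minimising the maximum distance — the
radius — to every input; the *closest substring problem* (CSSP) asks for a
string of fixed length `L` minimising the maximum, over inputs, of its
minimum distance to any length-`L` contiguous window of that input. Both
problems are NP-hard for the distances considered here, so `rdclosest`
approximates them with genetic algorithms. Typical uses are consensus
finding and motif search in DNA, where the inputs are prefixes of
mitochondrial genomes or other homologous regions.

Three metrics are supported as the search objective: rank distance,
Hamming distance and Levenshtein (edit) distance. Hamming and Levenshtein
are standard; rank distance is the interesting one.

## Rank distance

A ranking is an ordered list of distinct objects; the object at position
`p` in a ranking of length `n` has *order* `n + 1 - p`, so the top object
carries the highest order and, by convention, an object absent from a
ranking has order 0 there. The rank distance between two rankings is the
L1 distance between their order vectors over the union of their objects.
For two permutations of the same objects this is the classical Spearman
footrule.

A string becomes a ranking by *annotation*: the i-th occurrence of a
letter is tagged with index i, making every symbol unique:

```{r}
annotate("alibaba")
```

The rank distance between two strings is then the rank distance between
their annotated rankings: the i-th `A` of one string pairs with the i-th
`A` of the other and contributes the gap between their positions (for
equal-length strings), while an unpaired occurrence contributes its own
order. Because orders decay towards the end of the string, a composition
mismatch near the end is cheap and one near the front is expensive. The
distance is a true metric (it is an L1 distance in the order-vector
embedding), is defined for strings of unequal length, and — unlike the
edit distance — needs no alignment: it is computed in one linear pass per
string.

Two computation paths are provided and tested against each other:
`rank_distance()` follows the definition through explicit annotation
objects, and `rank_distance_linear()` (used by the searches) collects
per-letter occurrence positions in compiled code.

The absent-symbol convention deserves a note, because the choice is not
innocuous. An alternative convention — an unpaired symbol contributes its
*position* rather than its order — also yields a metric and also reduces
to the footrule on permutations. We adopted the order convention for two
reasons. First, it is the one under which the distance is literally "the
sum of the absolute differences between the orders" of the annotated
characters, with the missing-object order defined once for all partial
rankings. Second, it is the convention under which the substring search
behaves sensibly: under the position convention a candidate whose
composition lacks a late-position symbol is penalised by roughly the
full string length, which riddles the windowed fitness landscape with
strict local optima (no improving point mutation exists at them) and
leaves the search stranded far from a known optimum; under the order
convention those mismatches cost little, the landscape has a broad
basin, and the acceptance runs on the bundled artificial benchmark
attain the known optimum.

## The closest string search (`run_csp_ga()`)

**Encoding.** After annotation every symbol of a string is unique, so a
string is a permutation of its annotated symbols. `composition_map()`
fixes a canonical numbering (letters alphabetical, occurrence indices
ascending) of the composition of the *first* input string; a candidate is
then exactly a permutation of `1..m`, and `decode_string()` maps any such
permutation back to a string with that composition. The first input's
composition pins down the search space when the inputs disagree; this is
a deliberate, deterministic choice — the objective itself is computed on
the decoded strings and does not depend on it.

**Crossover.** Each recombination applies three order-based forms to a
pair of parents: keep a prefix, keep a suffix (both share one fresh cut,
uniform on `1..m-1`), or keep both ends (a fresh ordered pair of cuts);
in every form the remaining positions are filled with the missing values
in the relative order they occur in the other parent, so children are
always valid permutations. The two fittest of the six children replace
the parents (ties broken in generation order). Using three forms at once
avoids the bias of any single form, which can only reorder one flank and
drags the population towards candidates that are good on one side only.

**Mutation.** A mutation event swaps the values at two random positions.

**Selection.** Candidates are sorted best-first (stable sort) and each of
the `P` slots of the next generation is filled independently by drawing
an index from a half-normal density over the sorted index scale:
`i = floor(|N(0, sd^2)| * P) + 1`, with draws of magnitude 1 or more
rejected. Good candidates are typically selected several times and the
tail may never be selected. The scale parameter `selection_stddev`
(default 0.3, as a fraction of the list) controls the selection pressure;
the default concentrates roughly two thirds of the draws on the best 30%
of the population, and small changes to it did not change any qualitative
behaviour in our calibration runs. `selection_stddev = 0` degenerates to
always selecting the best candidate.

**Loop.** Per generation: `floor(p_c * P)` chromosomes are drawn without
replacement and paired consecutively for crossover (an odd leftover is
returned unchanged), every chromosome then receives
`Binomial(length, p_m)` mutation events, the population is evaluated, and
selection forms the next generation. The mutation probability is
*per position*: across the reference parameter sets the published rates
scale inversely with chromosome length (0.02–0.03 at length 24 down to
0.00005 at length 16000, a constant 0.4–1 expected mutations per
chromosome), which identifies the intended model, and it is the classic
per-base point-mutation model in any case. The best candidate ever
evaluated is tracked outside the population and reported; there is no
forced elitist copy inside the population, so the per-generation trace
(`generation`, `gen_best`, `best_so_far`) reflects the undisturbed
dynamics while the reported best is monotone by construction.

**Fitness.** `max_distance_to_set()` of the decoded candidate — the
radius. Values are memoised per permutation; the cache is an observable
no-op (a seeded run is bit-identical with the cache disabled, which the
suite asserts).

## The closest substring search (`run_cssp_ga()`)

Chromosomes are plain length-`L` strings over the alphabet. Crossover is
one-point: prefixes stay, suffixes swap, and the children replace the
parents unconditionally. A mutation event redraws one position uniformly
from the alphabet minus the current letter. Selection and the generation
loop are identical to the closest string search. The fitness is the
windowed objective: the maximum over inputs of the minimum distance to
any length-`L` window (`cssp_fitness()`), computed window-by-window in
compiled code and memoised per candidate string. Windows have length
exactly `L` for all three metrics, including Levenshtein — one uniform
fitness semantics rather than a variable-window edit distance.

## Synthetic data

`random_dna()` draws uniform i.i.d. nucleotides; `plant_common_substring()`
overwrites one randomly placed window of each of several uniform
backgrounds with the same random block, so the planted block is a common
window of every input and the optimal CSSP distance is 0 by construction
for every metric. Generator seeds are local (the caller's RNG stream is
saved and restored), so fixture identity never depends on GA settings.

What the generator does *not* emulate: real homologous sequences are not
i.i.d. — related mtDNA regions share long, imperfect conserved stretches,
so a real common motif is typically embedded in a much longer
nearly-common context. A planted block of length exactly `L` in an
otherwise independent background is therefore *harder* than the
biological situation it abstracts: exactly one window phase per input is
optimal, and a search that locks onto a phase-shifted copy of the block
(whose few mismatches sit at the cheap end of the rank scale) must cross
a fitness barrier to re-phase. Passing planted-recovery tests at small
sizes shows the machinery works; failure to recover exact-length needles
at large `n` says little about performance on real conserved DNA, where
shared stretches longer than `L` make many phases optimal.

## Reference benchmarks and problem sizes

The package embeds, verbatim, the published reference materials it can
reproduce without downloads: two structured artificial sequences (100 and
90 nt) sharing the exact window `T^25 G^5`, the worked recombination and
mutation examples on three length-9 chromosomes, and the printed closest
strings/substrings with their achieved distances for the mtDNA benchmarks
(`reference_fixtures()`). The artificial benchmark runs the substring
search with population 500, 100 generations, crossover probability 0.36,
mutation probability 0.02 and `L = 30`; following the reference protocol
each setting is run 10 times, the reported value is the distance of the
best candidate produced, and the run-wise distances are logged to show
how reproducible it is. At these sizes one run takes a few
seconds on one CPU; the test suite uses the same sizes for the
acceptance checks and much smaller ones (populations 20–150, lengths
4–10, exhaustive enumerations up to `m = 5` and alphabet-2 strings up to
length 4) everywhere else.

The mtDNA benchmarks need the EMBL records (accessions in
`reference_fixtures()$accessions`); `scripts/fetch_accessions.R`
downloads them, the shipped `testcase*.cfg` files hold the published
parameter sets, and `verify_printed_result()` recomputes any printed
distance from its candidate without running a search. Nothing in the
package or its tests requires the network.

## Numerical and edge-case choices

* Positions are 1-based everywhere: rankings, annotations, window
  offsets, cut points.
* Inputs are uppercased at the I/O and search boundary; characters
  outside the configured alphabet (including IUPAC ambiguity codes) are a
  hard error naming the character and position, never silently mapped.
* Hamming on unequal lengths is an error, never padded; rank and
  Levenshtein accept unequal lengths (the closest string search itself
  requires equal-length inputs).
* Ties are broken stably everywhere (first encountered wins): child
  ranking in recombination, the selection sort, and the best-so-far
  update (strictly-better only).
* One seeded RNG stream drives a whole run; two runs with the same
  configuration are bit-identical, and the fitness cache provably does
  not affect results.
* "First k nucleotides" means the first k characters of the deposited
  record read from FASTA — no reverse-complementing, no feature-aware
  trimming.

## Known limitations

* The searches are heuristics: the reported radius is an upper bound on
  the true optimum, and on needle-like instances (exact-length planted
  blocks) the substring search often converges to a phase-shifted
  near-optimum rather than the planted zero.
* The selection density's scale is a calibrated default, not a printed
  constant; runs are comparable across metrics only under a fixed
  configuration.
* Weighted, local or circular rank distances, variable-length windows,
  gapped motifs and exact (ILP / branch-and-bound) solvers are out of
  scope.
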