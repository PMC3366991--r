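# FASTA prefix input, experiment specification, configuration files,
# dispatch to the two searches, and independent re-verification of
# reported distances.

#' Read the prefix of the first FASTA record
#'
#' Reads a FASTA file and returns the first k characters of the first
#' record's sequence (the k nucleotides closest to the 5' end, as deposited
#' -- no reverse-complementing, no feature-aware trimming), uppercased.
#' Characters outside `alphabet` are a hard error naming the character and
#' its position.
#'
#' @param path Path to a FASTA file.
#' @param k Prefix length; must not exceed the first record's length.
#'   `NULL` returns the whole first record.
#' @param alphabet Allowed letters; defaults to [dna_alphabet()].
#' @return A length-`k` string.
#' @export
read_fasta_prefix <- function(path, k = NULL, alphabet = dna_alphabet()) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L)
    stop(sprintf("no FASTA records in %s", path), call. = FALSE)
  s <- toupper(as.character(recs[[1L]]))
  s <- gsub("[[:space:]]", "", s)
  if (!is.null(k)) {
    if (nchar(s) < k)
      stop(sprintf("first record of %s has %d characters; %d requested",
                   path, nchar(s), k), call. = FALSE)
    s <- substr(s, 1L, k)
  }
  .string_codes(s, alphabet)  # validates; errors name character + position
  s
}

#' Specify a closest string / closest substring experiment
#'
#' Bundles the inputs (inline strings, or FASTA paths plus a prefix
#' length) with the problem kind and the GA parameters. File existence is
#' checked when the experiment is run, not when it is specified, so
#' configuration files can ship without their data.
#'
#' @param name Short experiment name.
#' @param problem `"csp"` (closest string) or `"cssp"` (closest substring).
#' @param inputs Character vector of inline input strings (alternative to
#'   `fasta`).
#' @param fasta Character vector of FASTA paths (alternative to `inputs`).
#' @param prefix_length Number of leading nucleotides taken from each FASTA
#'   record; `NULL` uses each whole first record.
#' @param substring_length Candidate length L (`"cssp"` only).
#' @param metric,population_size,generations,crossover_prob,mutation_prob,selection_stddev,seed
#'   Passed to [ga_config()].
#' @param long_running Informational flag for benchmark-scale settings.
#' @return An object of class `"experiment_spec"`.
#' @export
experiment_spec <- function(name, problem = c("csp", "cssp"),
                            inputs = NULL, fasta = NULL,
                            prefix_length = NULL, substring_length = NULL,
                            metric = "rank", population_size, generations,
                            crossover_prob = 0.36, mutation_prob = 0.02,
                            selection_stddev = 0.3, seed = NULL,
                            long_running = FALSE) {
  problem <- match.arg(problem)
  if (is.null(inputs) == is.null(fasta))
    stop("provide exactly one of 'inputs' or 'fasta'")
  if (problem == "cssp") {
    if (is.null(substring_length))
      stop("'substring_length' is required for the closest substring problem")
    if (!is.null(prefix_length) && substring_length > prefix_length)
      stop("'substring_length' must not exceed 'prefix_length'")
  }
  cfg <- ga_config(population_size, generations, crossover_prob,
                   mutation_prob, selection_stddev, metric, seed)
  structure(list(name = name, problem = problem, inputs = inputs,
                 fasta = fasta, prefix_length = prefix_length,
                 substring_length = substring_length, config = cfg,
                 long_running = isTRUE(long_running)),
            class = "experiment_spec")
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf("<experiment_spec '%s'> problem=%s", x$name, x$problem))
  if (!is.null(x$substring_length))
    cat(sprintf(" L=%d", x$substring_length))
  if (!is.null(x$fasta))
    cat(sprintf(" fasta=[%s] prefix=%d", paste(x$fasta, collapse = ", "),
                x$prefix_length))
  else cat(sprintf(" inputs=%d strings", length(x$inputs)))
  cat("\n  "); print(x$config)
  invisible(x)
}

#' Read an experiment configuration file
#'
#' Parses a flat `key: value` text file (one pair per line, `#` comments
#' allowed) into an [experiment_spec()]. Recognised keys: `name`,
#' `problem`, `metric`, `population`, `generations`, `crossover_prob`,
#' `mutation_prob`, `selection_stddev`, `prefix_length`,
#' `substring_length`, `seed`, `long_running`, and either `inputs` or
#' `fasta` (comma-separated lists). Relative FASTA paths are resolved
#' against the config file's directory.
#'
#' @param path Path to the configuration file.
#' @param overrides Named list of values replacing those in the file
#'   (e.g. `list(metric = "hamming", seed = 7)`).
#' @return An [experiment_spec()].
#' @export
read_experiment_config <- function(path, overrides = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", lines))
  if (any(lengths(kv) != 3L))
    stop(sprintf("malformed line in %s: %s", path,
                 lines[which(lengths(kv) != 3L)[1L]]), call. = FALSE)
  vals <- stats::setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
  vals <- as.list(vals)
  vals[names(overrides)] <- lapply(overrides, as.character)

  get_num <- function(key, default = NULL) {
    if (is.null(vals[[key]])) return(default)
    as.numeric(vals[[key]])
  }
  split_list <- function(x) trimws(strsplit(x, ",", fixed = TRUE)[[1L]])
  fasta <- if (!is.null(vals$fasta)) {
    paths <- split_list(vals$fasta)
    ifelse(grepl("^/", paths), paths, file.path(dirname(path), paths))
  }
  experiment_spec(
    name = if (!is.null(vals$name)) vals$name else basename(path),
    problem = vals$problem,
    inputs = if (!is.null(vals$inputs)) split_list(vals$inputs),
    fasta = fasta,
    prefix_length = get_num("prefix_length"),
    substring_length = get_num("substring_length"),
    metric = if (!is.null(vals$metric)) vals$metric else "rank",
    population_size = get_num("population"),
    generations = get_num("generations"),
    crossover_prob = get_num("crossover_prob", 0.36),
    mutation_prob = get_num("mutation_prob", 0.02),
    selection_stddev = get_num("selection_stddev", 0.3),
    seed = get_num("seed"),
    long_running = isTRUE(as.logical(vals$long_running)))
}

# resolve an experiment's input strings (inline or FASTA prefixes)
.resolve_inputs <- function(spec, alphabet = dna_alphabet()) {
  if (!is.null(spec$inputs)) {
    inputs <- toupper(spec$inputs)
    if (!is.null(spec$prefix_length))
      inputs <- substr(inputs, 1L, spec$prefix_length)
    return(inputs)
  }
  vapply(spec$fasta, read_fasta_prefix, "", k = spec$prefix_length,
         alphabet = alphabet, USE.NAMES = FALSE)
}

#' Independently verify a reported closest string or substring
#'
#' Recomputes, without any search, the objective value of a candidate: for
#' the closest string problem its maximum distance to the inputs, for the
#' closest substring problem its windowed fitness ([cssp_fitness()]).
#' Used to check a search result, or any externally reported candidate,
#' against the inputs it was derived from.
#'
#' @param candidate Candidate string.
#' @param inputs Character vector of input strings.
#' @param metric One of `"rank"`, `"hamming"`, `"levenshtein"`.
#' @param problem `"csp"` or `"cssp"`.
#' @param L Candidate length for `"cssp"`; defaults to
#'   `nchar(candidate)`.
#' @param alphabet Allowed letters; defaults to [dna_alphabet()].
#' @return The achieved maximum distance, a non-negative number.
#' @export
verify_printed_result <- function(candidate, inputs,
                                  metric = "rank",
                                  problem = c("csp", "cssp"),
                                  L = NULL, alphabet = dna_alphabet()) {
  problem <- match.arg(problem)
  candidate <- toupper(candidate)
  inputs <- toupper(as.character(inputs))
  if (problem == "csp")
    return(max_distance_to_set(candidate, inputs, metric, alphabet))
  if (is.null(L)) L <- nchar(candidate)
  if (nchar(candidate) != L)
    stop("'candidate' must have length L for the closest substring problem")
  cssp_fitness(candidate, inputs, metric, alphabet)
}

#' Run an experiment
#'
#' Resolves the inputs, dispatches to [run_csp_ga()] or [run_cssp_ga()],
#' independently re-verifies the achieved distance from the returned
#' candidate via [verify_printed_result()], and optionally writes the
#' per-generation trace (TSV: `generation`, `gen_best`, `best_so_far`) and
#' a JSON result record to a directory.
#'
#' @param spec An [experiment_spec()] or a path to a configuration file.
#' @param out_dir Optional output directory; created if missing.
#' @param alphabet Allowed letters; defaults to [dna_alphabet()].
#' @param verbose Print a one-line summary when done.
#' @return A list of class `"run_result"`: `spec`, `best`, `distance`,
#'   `verified_distance` (always equal to `distance`), `trace`, `seed`,
#'   `elapsed` (seconds, informational only).
#' @export
run_experiment <- function(spec, out_dir = NULL,
                           alphabet = dna_alphabet(), verbose = FALSE) {
  if (is.character(spec)) spec <- read_experiment_config(spec)
  stopifnot(inherits(spec, "experiment_spec"))
  inputs <- .resolve_inputs(spec, alphabet)
  if (spec$problem == "csp" &&
      metric_requires_equal_length(spec$config$metric) &&
      length(unique(nchar(inputs))) != 1L)
    stop("equal-length inputs required for this metric in the closest string problem",
         call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  res <- if (spec$problem == "csp")
    run_csp_ga(inputs, spec$config, alphabet)
  else
    run_cssp_ga(inputs, spec$substring_length, spec$config, alphabet)
  elapsed <- proc.time()[["elapsed"]] - t0

  verified <- verify_printed_result(res$best, inputs, spec$config$metric,
                                    spec$problem, spec$substring_length,
                                    alphabet)
  if (verified != res$distance)
    stop(sprintf(
      "internal inconsistency: search reported %g but reverification gives %g",
      res$distance, verified))

  out <- structure(list(spec = spec, best = res$best,
                        distance = res$distance,
                        verified_distance = verified, trace = res$trace,
                        seed = spec$config$seed, elapsed = elapsed),
                   class = "run_result")
  if (!is.null(out_dir)) .write_run_result(out, out_dir)
  if (verbose)
    cat(sprintf("[%s] %s metric=%s distance=%g (%.1fs)\n", spec$name,
                spec$problem, spec$config$metric, out$distance, elapsed))
  out
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result '%s'> %s metric=%s\n", x$spec$name,
              x$spec$problem, x$spec$config$metric))
  cat(sprintf("  distance achieved: %g (independently verified)\n",
              x$distance))
  cat(sprintf("  best candidate:    %s\n", x$best))
  invisible(x)
}

.write_run_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(out_dir,
                    paste0(gsub("[^A-Za-z0-9._-]", "_", res$spec$name),
                           "_", res$spec$config$metric))
  utils::write.table(res$trace, paste0(stem, "_trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  record <- list(
    name = res$spec$name, problem = res$spec$problem,
    metric = res$spec$config$metric,
    substring_length = res$spec$substring_length,
    prefix_length = res$spec$prefix_length,
    population = res$spec$config$population_size,
    generations = res$spec$config$generations,
    crossover_prob = res$spec$config$crossover_prob,
    mutation_prob = res$spec$config$mutation_prob,
    selection_stddev = res$spec$config$selection_stddev,
    seed = res$seed, best = res$best, distance = res$distance)
  jsonlite::write_json(record, paste0(stem, "_result.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(c(trace = paste0(stem, "_trace.tsv"),
              result = paste0(stem, "_result.json")))
}
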