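#!/usr/bin/env Rscript
# Optional helper: download the mitochondrial genome records used by the
# accession-based benchmark configs (testcase1-4, 6-9) into a directory of
# FASTA files. Requires network access; nothing in the package or its test
# suite depends on these downloads.
#
# Usage: Rscript scripts/fetch_accessions.R [out_dir]

out_dir <- commandArgs(trailingOnly = TRUE)
out_dir <- if (length(out_dir) >= 1L) out_dir[[1L]] else "data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

library(rdclosest)
acc <- reference_fixtures()$accessions
base <- "https://www.ebi.ac.uk/ena/browser/api/fasta/"

for (organism in names(acc)) {
  id <- acc[[organism]]
  dest <- file.path(out_dir, paste0(id, ".fasta"))
  if (file.exists(dest)) {
    message(id, " already present, skipping")
    next
  }
  message("fetching ", organism, " (", id, ")")
  utils::download.file(paste0(base, id), dest, quiet = TRUE, mode = "wb")
}
message("done; FASTA files in ", normalizePath(out_dir))
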