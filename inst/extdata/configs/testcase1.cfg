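# Closest string, human-chimpanzee / human-donkey mtDNA prefixes (200 nt).
# FASTA files are not shipped; fetch them with scripts/fetch_accessions.R
# and point the paths below at the download directory.
name: testcase1
problem: csp
metric: rank
population: 2500
generations: 300
crossover_prob: 0.36
mutation_prob: 0.002
prefix_length: 200
fasta: data/V00662.fasta, data/D38116.fasta
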