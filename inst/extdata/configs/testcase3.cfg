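# Closest string, rat-house mouse mtDNA prefixes (150 nt).
name: testcase3
problem: csp
metric: rank
population: 1800
generations: 300
crossover_prob: 0.36
mutation_prob: 0.005
prefix_length: 150
fasta: data/X14848.fasta, data/V00711.fasta
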