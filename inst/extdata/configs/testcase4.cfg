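# Closest substring (24 nt), rat-house mouse mtDNA prefixes (300 nt).
name: testcase4
problem: cssp
metric: rank
population: 700
generations: 110
crossover_prob: 0.36
mutation_prob: 0.03
prefix_length: 300
substring_length: 24
fasta: data/X14848.fasta, data/V00711.fasta
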