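# Closest substring (24 nt), human-chimpanzee mtDNA prefixes (300 nt).
name: testcase2
problem: cssp
metric: rank
population: 500
generations: 100
crossover_prob: 0.36
mutation_prob: 0.02
prefix_length: 300
substring_length: 24
fasta: data/V00662.fasta, data/D38116.fasta
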