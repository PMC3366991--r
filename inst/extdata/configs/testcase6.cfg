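# Closest string, human-chimpanzee mtDNA prefixes (800 nt). Long-running.
name: testcase6
problem: csp
metric: rank
population: 7000
generations: 500
crossover_prob: 0.36
mutation_prob: 0.001
prefix_length: 800
fasta: data/V00662.fasta, data/D38116.fasta
long_running: true
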