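# Closest string, human-chimpanzee mtDNA prefixes (16000 nt). Long-running.
name: testcase9
problem: csp
metric: rank
population: 55000
generations: 2800
crossover_prob: 0.36
mutation_prob: 0.00005
prefix_length: 16000
fasta: data/V00662.fasta, data/D38116.fasta
long_running: true
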