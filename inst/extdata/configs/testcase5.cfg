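# Closest substring (30 nt) on the bundled artificial pair, which shares
# the exact window T^25 G^5; the optimum distance is 0 for every metric.
name: testcase5
problem: cssp
metric: rank
population: 500
generations: 100
crossover_prob: 0.36
mutation_prob: 0.02
substring_length: 30
fasta: ../artificial_seq1.fasta, ../artificial_seq2.fasta
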