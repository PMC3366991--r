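>artificial_seq2 structured test sequence (90 nt)
CCCCCCCCCCGGGGGGGGGGTTTTTCCCCCCCCCCCCCCCCCCTTTTTTTTTTTTTTTTT
TTTTTTTTGGGGGCCCCCCCCCCCCCCCCC
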