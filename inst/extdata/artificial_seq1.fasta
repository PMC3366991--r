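>artificial_seq1 structured test sequence (100 nt)
AAAAAAAAAAAATTTTTTTTTTTTTTTTTTTTTTTTTGGGGGAAAAAAAAAAAAAAAAAA
AAAAAAAAAGGGGGGGGGGTTTTTAAAAAAAAAAAAAAAA
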