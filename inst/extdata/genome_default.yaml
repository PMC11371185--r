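# Default karyotype: 19 homolog pairs, equal relative lengths,
# centromere at 0.45 of each pair.
n_pairs: 19
lengths: 1.0
centromere_fractions: 0.45
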