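protein_a	protein_b
GAL4	GAL80
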