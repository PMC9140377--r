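taxon	Ne_nuc	max_mtdna_divergence
synthetic_subspecies_A	9500	0.85
synthetic_subspecies_B	16800	1.42
synthetic_subspecies_C	21200	0.95
synthetic_subspecies_D	27400	1.65
synthetic_subspecies_E	33100	1.18
synthetic_subspecies_F	41800	1.55
synthetic_subspecies_G	52600	1.30
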