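entity	amino_acid	ratio
4Fe-4S	cysteine	2
4Fe-4S_biotin_synthase	arginine	2
2Fe-2S_Rieske	histidine	2
2Fe-2S_Rieske	cysteine	2
2Fe-2S	cysteine	4
haem_b	cysteine	1
haem_c	cysteine	2
Fe3_mono	cysteine	4
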