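locus	genotype	class	phr_min	phr_max	mean
RICA1b5	122/137	LLR	-0.54	-0.29	-0.39
RICA1b5	122/137	LR	-0.23	0.00	NA
RICA1b5	122/137	LRR	0.09	0.25	0.17
RICA1b5	123/137	LLR	-0.54	-0.29	-0.39
RICA1b5	123/137	LR	-0.23	0.00	NA
RICA1b5	123/137	LRR	0.09	0.25	0.17
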