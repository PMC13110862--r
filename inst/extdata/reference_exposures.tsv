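population	statistic	hed	serum_ng_ml
ART	min	0.1	NA
ART	median	3.5	NA
ART	max	172	NA
occupational	min	NA	426
occupational	median	NA	1231
occupational	max	NA	19564
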