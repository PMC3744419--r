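allele	size_bp	size_printed	origin
P1-rr-E20	8157	8157 bp	whole_ear
P1-rr-E45	203000	203 kb	whole_ear
P1-rr-E43	332000	332 kb	whole_ear
P1-rr-T1	460000	460 kb	twin_sector
P1-rr-E317	459000	459 kb	whole_ear
P1-rr-E3	802000	802 kb	whole_ear
P1-rr-E70	1000000	1.0 Mb	whole_ear
P1-rr-E10	3300000	3.3 Mb	whole_ear
P1-rr-T481	5300000	5.3 Mb	twin_sector
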