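##gff-version 3
chr	phispy-like	prophage_region	50100	105800	.	+	.	ID=regionB1
chr	phispy-like	prophage_region	310000	340000	.	+	.	ID=regionB2
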