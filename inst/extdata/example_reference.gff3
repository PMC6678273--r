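##gff-version 3
##source-version rtracklayer 1.62.0
##date 2026-09-09
planted_seed7	phageCurate	CDS	310	897	.	-	0	ID=-:310
planted_seed7	phageCurate	CDS	958	1491	.	+	0	ID=+:1491
planted_seed7	phageCurate	CDS	2119	2640	.	+	0	ID=+:2640
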