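program	left	right	strand
prog3	310	897	-
prog3	958	1491	+
prog3	2119	2640	+
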