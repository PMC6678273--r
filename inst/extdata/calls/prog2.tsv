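program	left	right	strand
prog2	958	1491	+
prog2	2119	2640	+
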