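start_coordinate	sd_score
897	-4.7
958	-2.4
2119	-3.3
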