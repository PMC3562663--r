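truth	i	M	o
i	7636	358	889
M	1799	9817	1504
o	916	518	6465
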