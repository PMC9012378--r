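tertile	ia_cases	ais_cases	controls
T1	7	36	213
T2	61	123	72
T3	182	63	11
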