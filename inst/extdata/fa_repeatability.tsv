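visit	R1	R2	R3	R4
1	0.525	0.551	0.592	0.535
2	0.562	0.585	0.604	0.540
3	0.563	0.614	0.607	0.566
4	0.597	0.617	0.628	0.602
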