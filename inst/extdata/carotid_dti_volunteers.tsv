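volunteer	age	lambda1	lambda1_sd	lambda2	lambda2_sd	md	md_sd	fa	fa_sd
V1	27	1.59e-3	0.52e-3	0.44e-3	0.32e-3	1.02e-3	0.36e-3	0.697	0.192
V2	29	1.84e-3	0.47e-3	0.55e-3	0.22e-3	1.19e-3	0.28e-3	0.659	0.147
V3	32	1.85e-3	0.69e-3	0.64e-3	0.36e-3	1.24e-3	0.50e-3	0.636	0.151
V4	33	2.29e-3	0.80e-3	0.71e-3	0.30e-3	1.50e-3	0.50e-3	0.653	0.118
V5	33	3.61e-3	2.60e-3	1.14e-3	0.52e-3	2.38e-3	1.49e-3	0.612	0.131
V6	34	3.10e-3	1.07e-3	1.11e-3	0.44e-3	2.11e-3	0.67e-3	0.592	0.145
V7	37	2.05e-3	0.77e-3	0.74e-3	0.43e-3	1.40e-3	0.54e-3	0.604	0.180
V8	41	2.31e-3	0.63e-3	1.04e-3	0.39e-3	1.68e-3	0.44e-3	0.500	0.148
V9	44	2.56e-3	0.65e-3	0.99e-3	0.48e-3	1.78e-3	0.50e-3	0.581	0.181
V10	45	2.34e-3	0.79e-3	0.91e-3	0.42e-3	1.63e-3	0.55e-3	0.571	0.165
V11	47	2.58e-3	0.66e-3	1.09e-3	0.41e-3	1.84e-3	0.46e-3	0.527	0.163
V12	57	2.22e-3	0.54e-3	0.88e-3	0.29e-3	1.55e-3	0.38e-3	0.563	0.118
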