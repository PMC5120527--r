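analysis	lambda1	lambda1_sd	lambda2	lambda2_sd	lambda3	lambda3_sd	md	md_sd	fa	fa_sd
2D	1.10e-3	0.08e-3	0.65e-3	0.10e-3	NA	NA	0.88e-3	0.08e-3	0.36	0.07
3D	1.07e-3	0.06e-3	0.64e-3	0.10e-3	0.62e-3	0.07e-3	0.78e-3	0.06e-3	0.32	0.04
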