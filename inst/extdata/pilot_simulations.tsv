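metric	value	n_reps	conditions
faces_wald_power	0.765	400	planted family-environment effect of 0.5 SD on the profile score at n=66, alpha=0.05, full interaction model
faces_wald_null_rate	0.0725	400	no planted effect, same model; Wald chi-square on t-derived statistics is mildly anticonservative at this n
pmps_prs_correlation_min	0.84	20	two-cohort generator, coupling 0.4, n=200 discovery + 200 target, p_T=0.05
pmps_prs_correlation_median	0.945	20	same conditions as above
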