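cohort	n_species	n_p450	n_bgc_species	n_bgc	n_p450_in_bgc
Streptomyces	203	5460	144	4457	1231
Mycobacterium	60	1784	60	898	204
Bacillus	128	507	128	1098	112
Cyanobacteria	114	341	103	770	27
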