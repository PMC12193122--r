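outcome	exposure	mediator	total_beta	total_lo	total_hi	indirect_beta	indirect_lo	indirect_hi	p_indirect	proportion_pct
RA overall	Relative sugar intake	MIP1b	0.704	0.054	1.355	-0.086	-0.144	-0.028	0.004	12.19
RA overall	Smoking initiation	TRAIL	0.369	0.306	0.432	-0.005	-0.010	0.000	0.033	1.41
Seropositive RA	Smoking initiation	Eotaxin	0.366	0.284	0.448	0.005	-0.001	0.011	0.097	1.42
Seropositive RA	Smoking initiation	TRAIL	0.366	0.284	0.448	-0.007	-0.013	-0.001	0.033	1.80
Seronegative RA	Relative sugar intake	MIP1b	0.989	0.302	1.676	-0.093	-0.156	-0.029	0.004	9.36
Seronegative RA	Coffee consumption	SCGFb	0.008	0.003	0.012	-0.001	-0.001	0.000	0.047	7.84
Seronegative RA	Smoking initiation	TRAIL	0.415	0.308	0.522	-0.008	-0.015	0.000	0.039	1.84
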