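mirna	adj_p	log2_fc	n_targets	nsr	tfp	utp
miR-204-5p	3.43e-08	-2.0896	21	13	0.2857	0.3846
miR-101-3p	1.26e-08	-1.0684	24	3	0.2917	0.3333
miR-145-5p	8.00e-25	-3.2157	12	3	0.2500	0.3333
miR-198	7.67e-05	1.2564	12	5	0.3333	0.2000
miR-152	3.67e-08	-1.0146	17	6	0.2941	0.1667
miR-130a-3p	NA	NA	NA	NA	NA	0
miR-363-3p	NA	NA	NA	NA	NA	0
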