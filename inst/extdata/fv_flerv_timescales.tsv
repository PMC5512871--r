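node	s_median	s_low	s_high	t_median	t_low	t_high	calibrated
I	0.031	0.017	0.048	0.96	0.69	1.21	TRUE
II	0.080	0.057	0.107	8.29	6.52	10.05	TRUE
III	0.126	0.097	0.163	16.52	13.33	19.61	TRUE
IV	0.160	0.123	0.199	31.60	25.36	37.85	TRUE
V	0.292	0.238	0.349	43.43	38.39	48.08	TRUE
VI	0.348	0.288	0.413	86.92	76.34	97.22	TRUE
VII	0.381	0.315	0.454	98.59	95.94	100.78	TRUE
VIII	0.436	0.357	0.523	100.95	98.40	103.83	TRUE
IX	0.559	0.464	0.660	103.92	99.73	109.09	TRUE
X	0.764	0.641	0.889	NA	NA	NA	FALSE
XI	0.908	0.771	1.056	NA	NA	NA	FALSE
XII	1.071	0.869	1.274	NA	NA	NA	FALSE
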