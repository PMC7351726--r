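compound_id	cell_line	ic50_uM	sd_uM
1	HepG2	>20	
1	LU-1	>20	
1	SW480	>20	
1	HL-60	>20	
1	HEK-293	>20	
3	HepG2	>20	
3	LU-1	>20	
3	SW480	>20	
3	HL-60	>20	
3	HEK-293	>20	
4	HepG2	>20	
4	LU-1	19.55	1.23
4	SW480	18.59	0.91
4	HL-60	15.27	0.35
4	HEK-293	16.22	0.33
2	HepG2	16.00	0.62
2	LU-1	16.36	1.05
2	SW480	15.65	0.74
2	HL-60	16.50	0.94
2	HEK-293	14.16	0.71
6a	HepG2	3.56	0.75
6a	LU-1	2.26	0.32
6a	SW480	3.36	0.64
6a	HL-60	2.39	0.46
6a	HEK-293	3.21	0.43
6b	HepG2	>20	
6b	LU-1	>20	
6b	SW480	>20	
6b	HL-60	>20	
6b	HEK-293	>20	
6c	HepG2	3.38	0.68
6c	LU-1	2.99	0.55
6c	SW480	3.8	0.52
6c	HL-60	1.43	0.22
6c	HEK-293	1.19	0.12
6d	HepG2	3.76	0.75
6d	LU-1	2.85	0.74
6d	SW480	4.46	1.18
6d	HL-60	3.40	0.76
6d	HEK-293	2.01	0.64
6e	HepG2	4.62	1.07
6e	LU-1	3.28	0.48
6e	SW480	4.66	0.92
6e	HL-60	3.27	0.37
6e	HEK-293	6.98	0.25
6f	HepG2	2.01	0.43
6f	LU-1	1.30	0.14
6f	SW480	2.54	0.25
6f	HL-60	0.98	0.12
6f	HEK-293	1.03	0.11
6g	HepG2	5.68	0.71
6g	LU-1	3.96	0.62
6g	SW480	4.10	0.57
6g	HL-60	4.82	0.46
6g	HEK-293	1.80	0.21
6h	HepG2	14.23	1.79
6h	LU-1	8.74	0.55
6h	SW480	14.13	1.18
6h	HL-60	6.50	0.98
6h	HEK-293	9.74	0.53
6i	HepG2	2.28	0.12
6i	LU-1	2.07	0.26
6i	SW480	3.43	0.84
6i	HL-60	1.28	0.34
6i	HEK-293	0.85	0.05
6k	HepG2	2.95	0.19
6k	LU-1	2.50	0.34
6k	SW480	2.91	0.13
6k	HL-60	1.29	0.14
6k	HEK-293	1.92	0.17
6l	HepG2	3.28	0.25
6l	LU-1	2.07	0.31
6l	SW480	3.03	0.11
6l	HL-60	1.28	0.16
6l	HEK-293	7.12	0.18
6m	HepG2	15.31	0.17
6m	LU-1	8.74	1.06
6m	SW480	14.36	0.72
6m	HL-60	15.96	0.38
6m	HEK-293	11.93	1.75
6n	HepG2	11.70	0.23
6n	LU-1	10.08	0.44
6n	SW480	12.54	0.53
6n	HL-60	10.44	0.84
6n	HEK-293	9.52	0.07
6o	HepG2	11.68	0.26
6o	LU-1	8.80	0.38
6o	SW480	11.16	0.76
6o	HL-60	9.39	0.45
6o	HEK-293	5.89	0.75
6p	HepG2	10.61	0.79
6p	LU-1	8.61	0.57
6p	SW480	11.71	0.48
6p	HL-60	11.25	1.04
6p	HEK-293	7.72	0.42
Ellipticine	HepG2	1.93	0.54
Ellipticine	LU-1	2.50	0.82
Ellipticine	SW480	1.76	0.63
Ellipticine	HL-60	2.19	1.12
Ellipticine	HEK-293	0.32	0.03
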