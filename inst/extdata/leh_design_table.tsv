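substrate	target	design_id	mutations	nac_rr	nac_ss	ee_reported
1a	RR	1A	M32L_M78W_I80V_L103F_F139W	5.63	0.000	100
1a	RR	43A	L74I_L103V_F134Y_F139W	3.86	0.040	98
1a	RR	59A	M78L_L103V_L114G_I116F_F139I	2.59	0.008	99
1a	RR	45A	M32L_L74I_L103V_L114W_I116L_F134G_F139W	2.44	0.000	100
1a	RR	46C	M32L_L103V_L114A_I116F_F139W	2.08	0.000	100
1a	SS	3A	M32L_L35W_I80A_I116V_F139W	0.280	36.5	-98
1a	SS	4C	M32L_L35W_I80G_V83I_I116V_F139W	0.208	24.1	-98
1a	SS	24A	M32A_M78I_I80F_L103I_I116V_F139L	0.248	23.6	-98
1a	SS	25A	M78I_I80F_L103I_I116V_F139L	0.080	19.4	-99
1a	SS	26A	L35F_M78F_I80G_I116V_F139W	0.240	19.3	-98
2a	RR	47B	M32L_L35M_M78I_I80L_V83L_I116M_F134Y	24.1	0.176	99
2a	RR	48A	M32L_L35G_M78L_I80W_L103I_F139L	9.00	0.152	97
2a	RR	45A	M32L_L74I_L103V_L114W_I116L_F134G_F139W	5.72	0.112	96
2a	RR	49A	L103V_L114W_I116L_F134G_F139W	4.14	0.048	98
2a	RR	50A	M32L_L103V_F134Y_F139M	2.90	0.040	97
2a	SS	30A	L74W_I80F_L103I_I116V_F139L	0.496	25.2	-96
2a	SS	31A	L35F_M78F_I80A_I116V_F139W	0.320	23.7	-97
2a	SS	32A	L35W_L74F_I80G_I116V_F139L	0.080	21.8	-99
2a	SS	33B	M32L_I80W_L103I_F139L	0.168	21.0	-98
2a	SS	26A	L35F_M78F_I80G_I116V_F139W	0.080	20.4	-99
3a	RR	51A	M32L_L35G_I80W_L103V_F139W	28.2	0.104	99
3a	RR	52A	M32L_L35M_M78I_L103I_L114M_I116F	24.9	0.144	99
3a	RR	60A	M32L_L35G_I80W_L103V_F139L	22.7	0.048	100
3a	RR	61B	M32A_I80V_L103V_L114W_I116V_F134G_F139L	22.1	0.136	99
3a	RR	38A	M32L_M78L_I80V_L103V_F134W_F139L	22.0	0.352	97
3a	SS	62A	M32L_I80V_L103V_L114W_I116A_F134G_F139L	0.016	15.5	-100
3a	SS	63B	M78I_I80L_L103V_L114W_I116V_F134G_F139L	0.240	15.4	-97
3a	SS	64C	M32A_L103V_L114W_I116A_F134G_F139L	0.152	15.3	-98
3a	SS	41B	M32L_L35M_L103I_L114M_I116F_F139L	0.072	15.0	-99
3a	SS	65B	L74I_M78F_L103V_L114A_I116V_F134W_F139M	0.008	14.7	-100
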