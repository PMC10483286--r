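sequence	accession	biovar	size_mb	total	coding	noncoding	mono	di	tri	tetra	penta	hexa
CP_04MAT	CP036469.1	Ovis	2.33801	53	49	4	1	0	24	22	3	3
CP_1002B	CP012837.1	Ovis	2.33831	54	49	5	2	0	24	22	3	3
CP_106A	CP003082.1	Equi	2.33835	54	48	6	0	0	24	21	6	3
CP_226	CP010889.1	Ovis	2.33783	53	50	3	0	0	25	21	3	4
CP_258	CP003540.3	Equi	2.33749	57	49	8	0	0	25	23	6	3
CP_262	CP012022.2	Equi	2.33757	48	44	4	0	0	22	23	1	2
CP_267	CP003407.1	Ovis	2.33790	54	50	4	1	0	25	21	3	4
CP_29156	CP010795.2	Ovis	2.33775	53	50	3	0	0	25	21	3	4
CP_31	CP003421.4	Equi	2.33727	53	47	6	0	0	24	23	4	2
CP_316	CP003077.2	Equi	2.33750	52	48	4	0	0	24	23	2	3
CP_32	CP015183.1	Equi	2.33730	55	47	8	0	0	24	23	6	2
CP_33	CP015184.1	Equi	2.33729	55	47	8	0	0	24	23	6	2
CP_34	CP015192.1	Equi	2.33733	55	47	8	0	0	24	23	6	2
CP_35	CP015185.1	Equi	2.33732	55	47	8	0	0	24	23	6	2
CP_36	CP015186.1	Equi	2.33734	54	46	8	0	0	23	23	6	2
CP_38	CP015187.1	Equi	2.33731	57	47	10	0	2	24	23	6	2
CP_38MAT	CP036457.1	Ovis	2.33771	53	48	5	2	0	24	21	3	3
CP_39	CP015188.1	Equi	2.33728	56	47	9	0	1	24	23	6	2
CP_43	CP015189.1	Equi	2.33756	56	46	10	0	2	23	23	6	2
CP_46	CP015190.1	Equi	2.33755	56	46	10	0	2	23	23	6	2
CP_48	CP015191.1	Equi	2.33735	55	46	9	0	1	23	23	6	2
CP_Cap1W	CP034411.1	Ovis	2.33817	53	49	4	1	0	24	22	3	3
CP_CAP3W	CP026500.1	Ovis	2.33818	52	49	3	0	0	24	22	3	3
CP_CAPJ4	CP026499.1	Ovis	2.33808	53	49	4	1	0	24	22	3	3
CP_CAPMI03	CP035717.1	Ovis	2.33812	51	48	3	0	0	23	22	3	3
CP_CIP	CP003061.3	Equi	2.33748	57	49	8	0	0	25	23	6	3
CP_Cp162	CP003652.3	Equi	2.33736	50	47	3	0	0	22	23	2	3
CP_E19	CP012136.1	Equi	2.33753	52	49	3	1	0	24	22	2	3
CP_E55	CP014341.1	Ovis	2.33829	55	51	4	2	0	25	23	2	3
CP_I19	CP002251.3	Ovis	2.33821	54	51	3	0	0	25	22	3	4
CP_I37	CP017384.1	Equi	2.33742	51	47	4	0	0	23	22	3	3
CP_MB11	CP013260.2	Equi	2.33741	52	48	4	0	0	24	23	2	3
CP_MB14	CP013261.1	Equi	2.33740	53	49	4	0	0	25	23	2	3
CP_MB20	CP016829.1	Equi	2.33739	54	50	4	1	0	24	24	2	3
CP_MB30	CP013262.2	Equi	2.33752	52	48	4	0	0	24	23	2	3
CP_MB66	CP013263.1	Equi	2.33737	53	49	4	0	0	24	24	2	3
CP_MEX1	CP017711.1	Ovis	2.33827	51	47	4	0	0	24	21	3	3
CP_MEX2	CP046644.1	Ovis	2.33809	51	47	4	0	0	24	21	3	3
CP_MEX25	CP013697.1	Ovis	2.33813	55	50	5	1	0	26	21	3	4
CP_MEX29	CP016826.1	Ovis	2.33780	55	51	4	1	0	25	22	3	4
CP_MEX30	CP017291.1	Equi	2.33751	57	50	7	3	1	24	24	2	3
CP_MEX31	CP017292.1	Equi	2.33754	54	48	6	0	2	24	23	2	3
CP_OVID04	CP035640.1	Ovis	2.33810	51	48	3	0	0	24	21	3	3
CP_OVIOS02	CP035679.1	Ovis	2.33793	53	49	4	1	0	24	22	3	3
CP_OVIZ01	CP035678.1	Ovis	2.33781	52	48	4	1	0	24	21	3	3
CP_PA01	CP013327.1	Ovis	2.33777	53	49	4	1	0	25	21	3	3
CP_PA02	CP015309.1	Ovis	2.33834	51	48	3	0	0	23	22	3	3
CP_PA04	CP019587.1	Ovis	2.33773	56	48	8	5	0	24	21	3	3
CP_PA07	CP024457.1	Ovis	2.33820	51	48	3	0	0	24	21	3	3
CP_PAT10	CP002924.1	Ovis	2.33830	56	51	5	2	0	25	22	3	4
CP_PAT14	CP047603.1	Ovis	2.33825	54	51	3	0	0	25	22	3	4
CP_PAT16	CP046641.1	Ovis	2.33815	54	51	3	0	0	25	22	3	4
CP_PO22241	CP013698.1	Ovis	2.33816	53	49	4	1	0	25	21	3	3
CP_PO2695	CP012695.1	Ovis	2.33826	54	49	5	2	0	24	22	3	3
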