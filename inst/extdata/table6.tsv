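author	year	gene	variant	comparison	maf	odds_ratio	ci_lower	ci_upper	p_value	study_type	ethnicity	subtype	n_cases	n_controls	n_studies	par_printed	fprp_or1.5_1e-06	bfdp_1e-06
Chang X	2018	NMUR2	rs72793414	A vs. G	0.1082	2.44	1.85	3.23	3.81E-10	gwas	Overall 2	overall	1212	13494	2	13.4804396578	0.541	0.743
Gormley P	2016	LRP1	rs11172113	C vs. T	0.3894	0.90	0.89	0.91	5.6E-49	gwas	Caucasian 22	overall	59674	316078	22	4.0517761638	–	6.011E-69
Gormley P	2016	PRDM 16	rs10218452	G vs. A	0.2264	1.11	1.10	1.13	5.3E-38	gwas	Caucasian 22	overall	59674	316078	22	2.4298861162	–	8.356E-22
Gormley P	2016	FHL5	rs67338227	T vs. A	0.0220	1.09	1.08	1.11	2.0E-27	gwas	Caucasian 22	overall	59674	316078	22	0.1976087347	–	4.435E-12
Gormley P	2016	TSPAN2	rs2078371	C vs. T	0.1252	1.11	1.09	1.13	4.1E-24	gwas	Caucasian 22	overall	59674	316078	22	1.3584908638	–	8.356E-22
Gormley P	2016	PHACTR1	rs9349379	G vs. A	0.3774	0.93	0.92	0.95	5.8E-22	gwas	Caucasian 22	overall	59674	316078	22	2.7134848426	2.310E-05	3.995E-03
Gormley P	2016	MEF2D	rs1925950	A vs. G	0.4277	1.07	1.06	1.09	9.1E-22	gwas	Caucasian 22	overall	59674	316078	22	2.9068711836	8.022E-07	1.695E-04
Gormley P	2016	SLC24A3	rs4814864	C vs. G	0.3021	1.07	1.06	1.09	2.2E-19	gwas	Caucasian 22	overall	59674	316078	22	2.0709065394	8.022E-07	1.695E-04
Gormley P	2016	FGF6	rs1024905	A vs. G	0.3165	1.06	1.04	1.08	2.1E-17	gwas	Caucasian 22	overall	59674	316078	22	1.8636100452	9.959E-04	0.150
Gormley P	2016	C7orf10	rs186166891	T vs. A	0.1631	1.09	1.07	1.12	9.7E-16	gwas	Caucasian 22	overall	59674	316078	22	1.4466644131	4.935E-04	6.048E-02
Gormley P	2016	PLCE1	rs10786156	G vs. C	0.4852	0.95	0.94	0.96	2.0E-14	gwas	Caucasian 22	overall	59674	316078	22	2.4863180765	–	3.846E-13
Gormley P	2016	KCNK5	rs10456100	T vs. C	0.1813	1.06	1.04	1.07	6.9E-13	gwas	Caucasian 22	overall	59674	316078	22	1.0760942468	–	3.376E-25
Gormley P	2016	HPSE2	rs12260159	A vs. G	0.1673	0.92	0.89	0.94	3.2E-10	gwas	Caucasian 22	overall	59674	316078	22	1.3565561475	2.982E-08	5.912E-06
Gormley P	2016	CFDP1	rs77505915	A vs. T	0.4898	1.05	1.03	1.06	3.3E-10	gwas	Caucasian 22	overall	59674	316078	22	2.3904576911	–	3.479E-15
Gormley P	2016	RNF213	rs17857135	C vs. T	0.2115	1.06	1.04	1.08	5.2E-10	gwas	Caucasian 22	overall	59674	316078	22	1.2530981840	9.959E-04	0.150
Gormley P	2016	NRP1	rs2506142	G vs. A	0.1865	1.06	1.04	1.07	1.5E-09	gwas	Caucasian 22	overall	59674	316078	22	1.1066169563	–	3.376E-25
Gormley P	2016	GPR149	rs13078967	C vs. A	0.0110	0.87	0.83	0.91	1.8E-09	gwas	Caucasian 22	overall	59674	316078	22	0.1432047828	1.260E-03	0.101
Gormley P	2016	SPINK2	rs7684253	T vs. C	0.4499	0.96	0.94	0.97	2.5E-09	gwas	Caucasian 22	overall	59674	316078	22	1.8325790934	1.154E-08	4.530E-06
Gormley P	2016	HEY2	rs1268083	C vs. T	0.4419	0.96	0.95	0.97	5.3E-09	gwas	Caucasian 22	overall	59674	316078	22	1.7994063059	1.154E-08	4.530E-06
Gormley P	2016	WSCD1	rs75213074	T vs. C	0.0094	0.89	0.86	0.93	7.1E-09	gwas	Caucasian 22	overall	59674	316078	22	0.1035070263	0.170	0.937
Gormley P	2016	GJA1	rs28455731	T vs. G	0.1302	1.06	1.04	1.08	7.3E-09	gwas	Caucasian 22	overall	59674	316078	22	0.7751445706	9.959E-04	0.150
Gormley P	2016	ITPK1	rs11624776	C vs. A	0.2278	0.96	0.94	0.97	7.9E-09	gwas	Caucasian 22	overall	59674	316078	22	0.9195792057	1.154E-08	4.530E-06
Gormley P	2016	ADAMTSL4	rs6693567	T vs. C	0.3037	1.05	1.03	1.06	1.2E-08	gwas	Caucasian 22	overall	59674	316078	22	1.4957864823	–	3.479E-15
Gormley P	2016	MED14	rs12845494	G vs. C	0.4114	0.96	0.95	0.97	1.7E-08	gwas	Caucasian 22	overall	59674	316078	22	1.6731330779	1.154E-08	4.530E-06
Gormley P	2016	LRRIQ3	rs1572668	G vs. A	0.4930	1.04	1.02	1.05	2.1E-08	gwas	Caucasian 22	overall	59674	316078	22	1.9338641980	8.882E-10	4.190E-07
Gormley P	2016	CARF	rs138556413	G vs. A	0.0104	0.88	0.84	0.92	2.3E-08	gwas	Caucasian 22	overall	59674	316078	22	0.1249559450	0.017	0.583
Gormley P	2016	ARMS2	rs2223089	C vs. G	0.1288	0.93	0.91	0.95	3.0E-08	gwas	Caucasian 22	overall	59674	316078	22	0.9098027819	2.310E-05	3.995E-03
Gormley P	2016	IGSF9B	rs561561	T vs. A	0.0827	0.94	0.92	0.96	3.4E-08	gwas	Caucasian 22	overall	59674	316078	22	0.4986744225	0.008	0.557
Gormley P	2016	NOTCH4	rs140002913	A vs. G	0.1150	0.91	0.88	0.94	3.8E-08	gwas	Caucasian 22	overall	59674	316078	22	1.0458242813	0.012	0.552
Anttila V	2013	PRDM16	rs2651899	C vs. T	0.4708	1.09	1.07	1.12	3.28E-14	gwas	Caucasian 19	overall	23285	95425	19	4.0649595346	4.935E-04	0.0605
Anttila V	2013	TSPAN2	rs12134493	A vs. C	0.0709	1.14	1.10	1.18	6.71E-14	gwas	Caucasian 19	overall	23285	95425	19	0.9828442876	9.548E-08	1.307E-05
Anttila V	2013	MEF2D	rs2274316	C vs. A	0.4289	1.07	1.04	1.09	3.14E-08	gwas	Caucasian 19	overall	23285	95425	19	2.9147892814	8.022E-07	1.695E-04
Anttila V	2013	TRPM8	rs7577262	A vs. G	0.2356	0.87	0.84	0.90	3.27E-13	gwas	Caucasian 19	overall	23285	95425	19	3.1595713513	8.188E-10	1.260E-07
Anttila V	2013	FHL5	rs13208321	A vs. T	0.2949	1.18	1.13	1.24	2.15E-12	gwas	Caucasian 19	overall	23285	95425	19	5.0406331131	6.115E-05	5.753E-03
Anttila V	2013	c7orf10	rs4379368	T vs. C	0.1961	1.11	1.08	1.15	1.46E-09	gwas	Caucasian 19	overall	23285	95425	19	2.1115517179	7.511E-03	0.424
Anttila V	2010	MTDH	rs1835740	C vs. T	0.3510	1.18	1.13	1.24	1.60E-11	gwas	Caucasian 7	overall	5950	50809	7	5.9425497094	8.139E-04	0.064
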