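LOCUS	CHR	BP	SNP	A1	A2	NEAREST_GENE	CONDFDR	CONJFDR	P_T2D	P_PCOS	Z_T2D	Z_PCOS
1	2	165737889	rs1509096	A	G	RNA5SP111	9.43e-03	9.53e-03	1.80e-05	1.40e-05	-4.29	-4.34
2	3	12349924	rs13061415	T	C	PPARG	3.09e-02	3.09e-02	6.60e-09	5.60e-05	5.80	4.03
3	3	123010775	rs4234212	T	C	ADCY5	4.64e-02	4.64e-02	5.80e-05	9.30e-05	-4.02	3.91
4	5	43618391	rs138484257	T	G	NNT	1.46e-02	9.69e-01	5.30e-01	9.80e-08	0.63	-5.33
5	8	11625205	rs804274	A	C	NEIL2	6.60e-03	7.47e-01	7.30e-02	2.10e-07	1.79	-5.19
6	11	30339461	rs7929660	A	G	ARL14EP	9.72e-03	5.65e-01	2.70e-02	6.80e-07	2.21	-4.97
7	11	32449098	rs5030174	A	G	WT1	1.67e-02	1.67e-02	1.50e-05	2.70e-05	4.33	-4.20
8	11	83562895	rs12808938	T	G	DLG2	2.43e-02	6.11e-01	3.50e-02	1.60e-06	2.11	4.80
9	16	53822502	rs7190396	T	G	FTO	1.97e-03	1.97e-03	7.60e-74	2.50e-06	-18.18	-4.71
10	16	81463967	rs2432581	A	G	CMIP	1.56e-02	3.32e-02	1.00e-04	2.50e-05	3.89	4.21
11	20	56125891	rs1474758	A	C	PCK1	2.49e-02	9.17e-01	3.50e-01	2.50e-07	-0.93	-5.16
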