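no	hgvs_c	hgvs_p	n_submissions	pct_plp_2022	pct_vus_2022	pct_blb_2022	varsome	canvig	consensus_2024
1	c.811G>A	p.Val271Met	15	0.0	6.7	93.3	LBV	LBV	B_LB
2	c.2207A>C	p.Glu736Ala	7	0.0	14.3	85.7	LBV	LBV	B_LB
3	c.2735A>G	p.Lys912Arg	6	0.0	16.7	83.3	LBV	LBV	B_LB
4	c.4766G>A	p.Arg1589His	6	0.0	16.7	83.3	LBV	LBV	B_LB
5	c.3818A>G	p.Gln1273Arg	4	0.0	25.0	75.0	LBV	LBV	B_LB
6	c.5585A>T	p.His1862Leu	4	0.0	25.0	75.0	LBV	VUS	B_LB
7	c.2155A>G	p.Lys719Glu	13	0.0	61.5	38.5	LBV	LBV	B_LB
8	c.441G>C	p.Leu147Phe	7	14.3	85.7	0.0	VUS	VUS	VUS
9	c.5521A>C	p.Ser1841Arg	5	40.0	60.0	0.0	LPV	LPV	P_LP
10	c.5165C>A	p.Ser1722Tyr	4	50.0	50.0	0.0	LPV	LPV	P_LP
11	c.5254G>C	p.Ala1752Pro	2	50.0	50.0	0.0	LPV	LPV	P_LP
12	c.5362G>T	p.Gly1788Cys	2	50.0	50.0	0.0	PV	LPV	P_LP
13	c.5090G>A	p.Cys1697Tyr	3	66.7	33.3	0.0	PV	LPV	P_LP
14	c.5258G>C	p.Arg1753Thr	3	66.7	33.3	0.0	LPV	LPV	P_LP
15	c.5143A>T	p.Ser1715Cys	5	80.0	20.0	0.0	PV	PV	P_LP
16	c.5408G>C	p.Gly1803Ala	5	80.0	20.0	0.0	VUS	LPV	P_LP
17	c.5332G>A	p.Asp1778Asn	6	83.3	16.7	0.0	PV	LPV	P_LP
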