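amp_id	sample_id	n_mussels	snc_total	snc_cds	frequency	ns_snc	omega	covered_codons
MytA	Pa	100	38	25	0.26	10	0.7	96
MytA	Vi	100	36	20	0.21	8	0.7	96
MytA	Ve	100	41	28	0.29	12	0.8	96
MytA	Ve nc	100	38	23	0.24	10	0.8	96
MytA	Ve ft	40	30	19	0.20	10	1.1	96
MytA	Ve nt	40	39	26	0.27	12	0.9	96
MytB	Pa	100	21	17	0.18	12	2.4	97
MytB	Vi	100	40	29	0.30	15	1.1	97
MytB	Ve	100	22	17	0.18	11	1.8	97
MytB	Ve nc	100	30	19	0.20	11	1.4	97
MytB	Ve ft	40	27	18	0.19	12	2.0	97
MytB	Ve nt	40	19	14	0.14	7	1.0	97
MytC	Pa	100	33	27	0.27	19	2.4	100
MytC	Vi	100	41	33	0.33	25	3.1	100
MytC	Ve	100	31	23	0.23	17	2.8	100
MytC	Ve nc	100	34	26	0.26	17	1.9	100
MytC	Ve ft	40	32	24	0.24	19	3.8	100
MytC	Ve nt	40	27	22	0.22	15	2.1	100
MytlB	Pa	100	11	5	0.05	1	0.3	100
MytlB	Vi	100	17	10	0.10	5	1.0	100
MytlB	Ve	100	16	9	0.09	3	0.5	100
MytlB	Ve nc	100	23	13	0.13	9	2.3	100
MytlB	Ve ft	40	15	10	0.10	5	1.0	100
MytlB	Ve nt	40	16	9	0.09	4	0.8	100
MytlC	Pa	100	8	1	0.01	0	0.0	100
MytlC	Vi	100	8	1	0.01	0	0.0	100
MytlC	Ve	100	11	2	0.02	0	0.0	100
MytlC	Ve nc	100	7	1	0.01	0	0.0	100
MytlC	Ve ft	40	6	1	0.01	0	0.0	100
MytlC	Ve nt	40	8	2	0.02	0	0.0	100
MytlD	Pa	100	23	16	0.17	15	15.0	92
MytlD	Vi	100	25	20	0.22	18	9.0	92
MytlD	Ve	100	21	12	0.13	11	11.0	92
MytlD	Ve nc	100	19	11	0.12	11	[11]	92
MytlD	Ve ft	40	18	13	0.14	13	[13]	92
MytlD	Ve nt	40	19	10	0.11	9	9.0	92
MytM	Pa	100	28	28	0.20	19	2.1	140
MytM	Vi	100	29	29	0.21	21	2.6	140
MytM	Ve	100	31	31	0.22	23	2.9	140
MytM	Ve nc	100	30	30	0.21	22	2.8	140
MytM	Ve ft	40	29	29	0.21	21	2.6	140
MytM	Ve nt	40	28	28	0.20	20	2.5	140
MGD1	Pa	100	28	21	0.26	14	2.0	81
MGD1	Vi	100	29	23	0.28	15	1.9	81
MGD1	Ve	100	28	21	0.26	14	2.0	81
MGD1	Ve nc	100	31	24	0.30	15	1.7	81
MGD1	Ve ft	40	28	22	0.27	15	2.1	81
MGD1	Ve nt	40	30	23	0.28	15	1.9	81
MGDt	Pa	100	43	12	0.19	11	11.0	63
MGDt	Vi	100	39	13	0.21	10	3.3	63
MGDt	Ve	100	40	12	0.19	10	5.0	63
MGDt	Ve nc	100	41	10	0.16	9	9.0	63
MGDt	Ve ft	40	35	12	0.19	10	5.0	63
MGDt	Ve nt	40	36	10	0.16	9	9.0	63
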