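amplicon_id	amp_id	tx_start	cds_start	cds_end	cds_frame_offset	cds_tx_start	signal_start	signal_end	mature_start	mature_end	cterm_start	cterm_end	cys_positions	fwd_primer	rev_primer
MytA_1	MytA	1	16	189	0	16	1	21	22	61	62	96	25,31,37,42,46,51,54,58	GGTGGGGAAGTGCAAATGGA	GCAGTCTATGATACACTCTG
MytA_2	MytA	124	1	180	0	16	1	21	22	61	62	96	25,31,37,42,46,51,54,58	TGTTCGATGGTGCCGTGCTA	CACAAGACTGAATTAAAACA
MytB_1	MytB	1	16	303	0	16	1	21	22	61	62	96	25,31,37,42,46,51,54,58	TTCCTTGTGTGTGGCATGCA	ACAGGAGAACTGTTAGAATA
MytC_1	MytC	1	16	195	0	16	1	21	22	61	62	100	25,31,37,42,46,51,54,58	GAGTAGAAATATGGAATGAA	GGCCCAGCAGAAATAGCCAC
MytC_2	MytC	135	1	181	1	16	1	21	22	61	62	100	25,31,37,42,46,51,54,58	GGGGTGTGTCTATCGTTGTA	GCCCAATTCGGATTACATCA
MytlB_1	MytlB	1	16	186	0	16	1	22	23	56	57	103	26,31,36,40,44,48,51,55	CGTTGGTCCTGAAAAATGAT	CATGTTGCACCAAAAGTGGC
MytlB_2	MytlB	157	1	168	0	16	1	22	23	56	57	103	26,31,36,40,44,48,51,55	TGCTGGGTGTGCCACTTTTG	CCAAAACGATTACAGCATCA
MytlC_1	MytlC	1	16	177	0	16	1	22	23	56	57	100	26,31,36,40,44,48,51,55	CCTAGAGCATATTCCATGCC	AATATGCAAACAGACGTCGC
MytlC_2	MytlC	148	1	168	0	16	1	22	23	56	57	100	26,31,36,40,44,48,51,55	ATAGAGTATTGCGACGTCTG	CCACATAACTTACGGGAAAT
MytlD_1	MytlD	1	16	306	0	16	1	22	23	56	57	97	26,31,36,40,44,48,51,55	TGTTCTTTCGGCATTATGCA	CCTCGCTGCGGATTAATAAC
MytM_1	MytM	52	1	420	0	16	1	22	23	76	77	152	26,30,35,40,44,49,54,58,63,67,71,75	TTGCAAAAATATATAGTTTT	TTGTTTCCAGTATTACCCCG
MGD1_1	MGD1	19	1	243	0	16	1	21	22	60	61	82	25,30,35,40,45,50,54,58	ATGACGTCCAAGGGGGACTA	GCATGATCGAAATTAAGTTT
MGDt_1	MGDt	1	16	198	0	16	1	23	24	61	NA	NA	27,32,37,42,47,52,56,60	TAAATTCAGGCGGTAATGAA	CTTATACACCTCTTATTTGC
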