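sample_id	amplicon_id	direction	barcode
Pa	MGD1_1	forward	TGCGA
Pa	MGD1_1	reverse	TGCGA
Pa	MGDt_1	forward	ATCGA
Pa	MGDt_1	reverse	ATCGA
Pa	MytA_1	forward	CGACA
Pa	MytA_1	reverse	CGACA
Pa	MytA_2	forward	GTACA
Pa	MytA_2	reverse	GTACA
Pa	MytB_1	forward	CAGCA
Pa	MytB_1	reverse	CAGCA
Pa	MytC_1	forward	GCGCA
Pa	MytC_1	reverse	GCGCA
Pa	MytC_2	forward	ATGCA
Pa	MytC_2	reverse	ATGCA
Pa	MytlB_1	forward	GATCA
Pa	MytlB_1	reverse	GATCA
Pa	MytlB_2	forward	TCTCA
Pa	MytlB_2	reverse	TCTCA
Pa	MytlC_1	forward	AGTCA
Pa	MytlC_1	reverse	AGTCA
Pa	MytlC_2	forward	GCAGA
Pa	MytlC_2	reverse	GCAGA
Pa	MytlD_1	forward	AGAGA
Pa	MytlD_1	reverse	AGAGA
Pa	MytM_1	forward	CTAGA
Pa	MytM_1	reverse	CTAGA
Ve	MGD1_1	forward	TCTGC
Ve	MGD1_1	reverse	TCTGC
Ve	MGDt_1	forward	AGTGC
Ve	MGDt_1	reverse	AGTGC
Ve	MytA_1	forward	GTCAC
Ve	MytA_1	reverse	GTCAC
Ve	MytA_2	forward	GAGAC
Ve	MytA_2	reverse	GAGAC
Ve	MytB_1	forward	ACGAC
Ve	MytB_1	reverse	ACGAC
Ve	MytC_1	forward	TATAC
Ve	MytC_1	reverse	TATAC
Ve	MytC_2	forward	GCTAC
Ve	MytC_2	reverse	GCTAC
Ve	MytlB_1	forward	CGTAC
Ve	MytlB_1	reverse	CGTAC
Ve	MytlB_2	forward	ACAGC
Ve	MytlB_2	reverse	ACAGC
Ve	MytlC_1	forward	CGAGC
Ve	MytlC_1	reverse	CGAGC
Ve	MytlC_2	forward	GTAGC
Ve	MytlC_2	reverse	GTAGC
Ve	MytlD_1	forward	CTCGC
Ve	MytlD_1	reverse	CTCGC
Ve	MytM_1	forward	CATGC
Ve	MytM_1	reverse	CATGC
Ve ft	MGD1_1	forward	TACAT
Ve ft	MGD1_1	reverse	TACAT
Ve ft	MGDt_1	forward	CTCAT
Ve ft	MGDt_1	reverse	CTCAT
Ve ft	MytA_1	forward	GCACG
Ve ft	MytA_1	reverse	GCACG
Ve ft	MytA_2	forward	AGACG
Ve ft	MytA_2	reverse	AGACG
Ve ft	MytB_1	forward	CTACG
Ve ft	MytB_1	reverse	CTACG
Ve ft	MytC_1	forward	GAGCG
Ve ft	MytC_1	reverse	GAGCG
Ve ft	MytC_2	forward	ACGCG
Ve ft	MytC_2	reverse	ACGCG
Ve ft	MytlB_1	forward	ACATG
Ve ft	MytlB_1	reverse	ACATG
Ve ft	MytlB_2	forward	CGATG
Ve ft	MytlB_2	reverse	CGATG
Ve ft	MytlC_1	forward	GTATG
Ve ft	MytlC_1	reverse	GTATG
Ve ft	MytlC_2	forward	CACTG
Ve ft	MytlC_2	reverse	CACTG
Ve ft	MytlD_1	forward	TGCTG
Ve ft	MytlD_1	reverse	TGCTG
Ve ft	MytM_1	forward	ATGTG
Ve ft	MytM_1	reverse	ATGTG
Ve nc	MGD1_1	forward	ACTAG
Ve nc	MGD1_1	reverse	ACTAG
Ve nc	MGDt_1	forward	TGTAG
Ve nc	MGDt_1	reverse	TGTAG
Ve nc	MytA_1	forward	AGATC
Ve nc	MytA_1	reverse	AGATC
Ve nc	MytA_2	forward	CTATC
Ve nc	MytA_2	reverse	CTATC
Ve nc	MytB_1	forward	TACTC
Ve nc	MytB_1	reverse	TACTC
Ve nc	MytC_1	forward	CGCTC
Ve nc	MytC_1	reverse	CGCTC
Ve nc	MytC_2	forward	ATCTC
Ve nc	MytC_2	reverse	ATCTC
Ve nc	MytlB_1	forward	TCGTC
Ve nc	MytlB_1	reverse	TCGTC
Ve nc	MytlB_2	forward	GACAG
Ve nc	MytlB_2	reverse	GACAG
Ve nc	MytlC_1	forward	CGCAG
Ve nc	MytlC_1	reverse	CGCAG
Ve nc	MytlC_2	forward	ATCAG
Ve nc	MytlC_2	reverse	ATCAG
Ve nc	MytlD_1	forward	CAGAG
Ve nc	MytlD_1	reverse	CAGAG
Ve nc	MytM_1	forward	GCGAG
Ve nc	MytM_1	reverse	GCGAG
Ve nt	MGD1_1	forward	GTCGT
Ve nt	MGD1_1	reverse	GTCGT
Ve nt	MGDt_1	forward	GATGT
Ve nt	MGDt_1	reverse	GATGT
Ve nt	MytA_1	forward	TCGAT
Ve nt	MytA_1	reverse	TCGAT
Ve nt	MytA_2	forward	ATGAT
Ve nt	MytA_2	reverse	ATGAT
Ve nt	MytB_1	forward	CATAT
Ve nt	MytB_1	reverse	CATAT
Ve nt	MytC_1	forward	AGTAT
Ve nt	MytC_1	reverse	AGTAT
Ve nt	MytC_2	forward	TCACT
Ve nt	MytC_2	reverse	TCACT
Ve nt	MytlB_1	forward	ATACT
Ve nt	MytlB_1	reverse	ATACT
Ve nt	MytlB_2	forward	TAGCT
Ve nt	MytlB_2	reverse	TAGCT
Ve nt	MytlC_1	forward	ACTCT
Ve nt	MytlC_1	reverse	ACTCT
Ve nt	MytlC_2	forward	CGTCT
Ve nt	MytlC_2	reverse	CGTCT
Ve nt	MytlD_1	forward	TGAGT
Ve nt	MytlD_1	reverse	TGAGT
Ve nt	MytM_1	forward	AGCGT
Ve nt	MytM_1	reverse	AGCGT
Vi	MGD1_1	forward	CACAC
Vi	MGD1_1	reverse	CACAC
Vi	MGDt_1	forward	AGCAC
Vi	MGDt_1	reverse	AGCAC
Vi	MytA_1	forward	TATGA
Vi	MytA_1	reverse	TATGA
Vi	MytA_2	forward	ACTGA
Vi	MytA_2	reverse	ACTGA
Vi	MytB_1	forward	CGTGA
Vi	MytB_1	reverse	CGTGA
Vi	MytC_1	forward	TCATA
Vi	MytC_1	reverse	TCATA
Vi	MytC_2	forward	ATATA
Vi	MytC_2	reverse	ATATA
Vi	MytlB_1	forward	GACTA
Vi	MytlB_1	reverse	GACTA
Vi	MytlB_2	forward	AGCTA
Vi	MytlB_2	reverse	AGCTA
Vi	MytlC_1	forward	CTCTA
Vi	MytlC_1	reverse	CTCTA
Vi	MytlC_2	forward	TAGTA
Vi	MytlC_2	reverse	TAGTA
Vi	MytlD_1	forward	ACGTA
Vi	MytlD_1	reverse	ACGTA
Vi	MytM_1	forward	GTGTA
Vi	MytM_1	reverse	GTGTA
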