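gene	alleles	guide	n_genotyped	n_ki	lethal	marker
clik-1	sy1084,sy1085	CTCTGGCTCTTGGTTCTCGT	46	24	FALSE	dpy-10
clik-2	sy1122,sy1123	GTATCCTTGCTTCTTGTCCT	105	28	TRUE	dpy-10
clik-3	sy1082,sy1083	GTCACGTGGTGTTCCGAAAC	46	6	FALSE	dpy-10
clik-3	sy1086,sy1087	ATTGCTTGGCACCTCGACGG	38	13	FALSE	dpy-10
T05C3.2	sy1080,sy1081	AGAACGAAACGCGCTAATGG	45	16	FALSE	dpy-10
cul-3	sy1153,s1154	ACTTTTGAAGCGTGCCATAC	40	12	TRUE	dpy-10
dlg-1	sy1155,sy1156	ACACTCCTACAACAGTCGTC	46	17	TRUE	dpy-10
ubq-1	sy1157,sy1158	AAAAACTATCACCCTGGAGG	19	2	TRUE	dpy-10
hpo-29	sy1159,sy1160	ATCTCCGTTCATATGTCTGC	12	2	TRUE	dpy-10
Y106G6H.8	sy1076,sy1077	AGGCCAGCCAGACGAATAAT	24	21	FALSE	dpy-10
aex-2	sy1078,sy1079	ATTACTGCAGCGACATGGGG	16	7	FALSE	dpy-10
Y71H2AM.20	sy1176,sy1177	TCTCCTAGCCAGCGTTCTTC	22	4	TRUE	dpy-10
set-16	sy1178,sy1179	CTGACGTTGTTGCTGCATGG	23	7	TRUE	dpy-10
C01B10.10	sy1114,sy1115	GCTCTGGGTCCATGTTGAAT	24	20	FALSE	dpy-10
C56G2.15	sy1120,sy1121	ACGACATTGGAGGGGACTGA	23	21	FALSE	dpy-10
C01B10.4	sy1131,sy1132	CATTTGGAAGGTGCAGAGAT	23	23	FALSE	dpy-10
C23H4.2	sy1163,sy1164	GCTTTGCAAACGGAACACTC	23	18	FALSE	dpy-10
C04G6.4	sy1165,sy1166	ATATTTGGCTGGAGAACTGG	24	15	FALSE	unc-58
ttc-36	sy1167,sy1168	CGAGAGAGAAGGTGTCGCGT	24	14	FALSE	unc-58
ZC376.2	sy1170,sy1171	GGAGGCGAAGGAGTATAAAG	24	19	FALSE	dpy-10
cpn-4	sy1172,sy1173	TGTTGAAGCTGGATACTTGT	24	13	FALSE	dpy-10
Y55F3BL.4	sy1174,sy1175	CTGGTCACTGGTAGAAAAGC	23	20	FALSE	unc-58
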