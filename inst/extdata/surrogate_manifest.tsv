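class_index	class_name	motif	weight
1	P Promoter	ACCTTA	0.1
1	P Promoter	GTCAGT	0.172
1	P Promoter	GTCTCT	0.18
1	P Promoter	TGGTCT	0.111
2	E1 Stem cell enhancer	CAGCAG	0.122
2	E1 Stem cell enhancer	TGTCGG	0.236
2	E1 Stem cell enhancer	CATTGA	0.111
2	E1 Stem cell enhancer	CATACA	0.17
3	E2 Multi-tissue enhancer	TGCAGG	0.228
3	E2 Multi-tissue enhancer	ACCATT	0.118
3	E2 Multi-tissue enhancer	GTATCA	0.228
3	E2 Multi-tissue enhancer	GGTTTC	0.133
4	E3 Brain / muscle enhancer	GGGGGT	0.062
4	E3 Brain / muscle enhancer	TGTATG	0.237
4	E3 Brain / muscle enhancer	TTGGGC	0.113
4	E3 Brain / muscle enhancer	CGCGCA	0.182
5	E4 Multi-tissue enhancer	ATCCAA	0.19
5	E4 Multi-tissue enhancer	CTCGTG	0.153
5	E4 Multi-tissue enhancer	GACAGA	0.236
5	E4 Multi-tissue enhancer	CTATCT	0.172
6	E5 B-cell-like enhancer	CTTAGT	0.198
6	E5 B-cell-like enhancer	ACACGC	0.096
6	E5 B-cell-like enhancer	TAACTG	0.191
6	E5 B-cell-like enhancer	CTGGCC	0.059
7	E6 Weak epithelial enhancer	TACCCG	0.232
7	E6 Weak epithelial enhancer	ATTCAT	0.183
7	E6 Weak epithelial enhancer	CCTATC	0.065
7	E6 Weak epithelial enhancer	CATGAT	0.05
8	E7 Monocyte enhancer	GGTGCG	0.222
8	E7 Monocyte enhancer	AAGGAA	0.144
8	E7 Monocyte enhancer	AGCTGC	0.245
8	E7 Monocyte enhancer	ACCTGT	0.174
9	E8 Weak multi-tissue enhancer	GTAGGG	0.194
9	E8 Weak multi-tissue enhancer	ACCGTC	0.108
9	E8 Weak multi-tissue enhancer	CAGCGC	0.181
9	E8 Weak multi-tissue enhancer	TACATA	0.078
10	E9 Liver / intestine enhancer	TCCATA	0.122
10	E9 Liver / intestine enhancer	TGTTCT	0.186
10	E9 Liver / intestine enhancer	TAGTCG	0.206
10	E9 Liver / intestine enhancer	AATAGA	0.185
11	E10 Brain enhancer	GTGCCG	0.237
11	E10 Brain enhancer	CCCGCA	0.221
11	E10 Brain enhancer	CTTCAG	0.06
11	E10 Brain enhancer	AAGAAC	0.211
12	E11 T-cell enhancer	AACTCT	0.099
12	E11 T-cell enhancer	CCTAGC	0.157
12	E11 T-cell enhancer	TTGACC	0.192
12	E11 T-cell enhancer	ACTCCC	0.105
13	E12 Erythroblast-like enhancer	GACACC	0.238
13	E12 Erythroblast-like enhancer	AGATCC	0.236
13	E12 Erythroblast-like enhancer	GGGGGG	0.183
13	E12 Erythroblast-like enhancer	TACTGA	0.242
14	TN1 Transcribed region 1	ACCCGA	0.136
14	TN1 Transcribed region 1	CAGAGG	0.218
14	TN1 Transcribed region 1	AGATGC	0.187
14	TN1 Transcribed region 1	TAGGAG	0.238
15	TN2 Transcribed region 2	AGTAGC	0.069
15	TN2 Transcribed region 2	TAAATC	0.086
15	TN2 Transcribed region 2	CTAGTG	0.116
15	TN2 Transcribed region 2	GTGTAT	0.096
16	TN3 Transcribed region 3	GTGATG	0.239
16	TN3 Transcribed region 3	TTTTGT	0.2
16	TN3 Transcribed region 3	AGGGAC	0.229
16	TN3 Transcribed region 3	TACGTT	0.059
17	TN4 Transcribed region 4	CAGACA	0.123
17	TN4 Transcribed region 4	ATCCCC	0.222
17	TN4 Transcribed region 4	GCTAAG	0.21
17	TN4 Transcribed region 4	GCGAAT	0.146
18	L1 Low signal 1	AGAAGA	0.1
18	L1 Low signal 1	TAGCCA	0.167
18	L1 Low signal 1	CACTGG	0.183
18	L1 Low signal 1	GGATTG	0.159
19	L2 Low signal 2	CCTGAT	0.092
19	L2 Low signal 2	AAACGA	0.157
19	L2 Low signal 2	CTCCAA	0.233
19	L2 Low signal 2	GTTGGT	0.077
20	L3 Low signal 3	GACGAA	0.16
20	L3 Low signal 3	CGACGC	0.195
20	L3 Low signal 3	CTCAGC	0.126
20	L3 Low signal 3	AAGTGT	0.111
21	L4 Low signal 4	AGCGAA	0.235
21	L4 Low signal 4	CACTCG	0.2
21	L4 Low signal 4	GAGGTA	0.149
21	L4 Low signal 4	GAACGC	0.064
22	L5 Low signal 5	AGGATC	0.246
22	L5 Low signal 5	CCACAA	0.097
22	L5 Low signal 5	TACATC	0.167
22	L5 Low signal 5	TTCATA	0.177
23	L6 Low signal 6	ATGCTC	0.075
23	L6 Low signal 6	TGACTC	0.113
23	L6 Low signal 6	TTGCCC	0.142
23	L6 Low signal 6	GTATAG	0.07
24	L7 Low signal 7	CGATAT	0.192
24	L7 Low signal 7	ACTCAA	0.156
24	L7 Low signal 7	TCGACC	0.207
24	L7 Low signal 7	TACACC	0.237
25	L8 Low signal 8	TCTAAG	0.114
25	L8 Low signal 8	CAGGTT	0.133
25	L8 Low signal 8	ATCGAA	0.104
25	L8 Low signal 8	AGTGCC	0.241
26	HET1 Heterochromatin 1	CGACAC	0.126
26	HET1 Heterochromatin 1	TAGTCT	0.178
26	HET1 Heterochromatin 1	TGTCTT	0.103
26	HET1 Heterochromatin 1	CGACCA	0.18
27	HET2 Heterochromatin 2	GTTGCT	0.071
27	HET2 Heterochromatin 2	TCCGCT	0.163
27	HET2 Heterochromatin 2	TTAGAC	0.111
27	HET2 Heterochromatin 2	GTTTTG	0.204
28	HET3 Heterochromatin 3	GATTAA	0.148
28	HET3 Heterochromatin 3	TATCTT	0.067
28	HET3 Heterochromatin 3	GATCGT	0.11
28	HET3 Heterochromatin 3	CCATGA	0.068
29	HET4 Heterochromatin 4	GGGGGC	0.07
29	HET4 Heterochromatin 4	TATTGG	0.158
29	HET4 Heterochromatin 4	CAAGCG	0.162
29	HET4 Heterochromatin 4	CATGGC	0.054
30	HET5 Heterochromatin 5	CTGGTC	0.223
30	HET5 Heterochromatin 5	AGACAG	0.111
30	HET5 Heterochromatin 5	GTTATT	0.169
30	HET5 Heterochromatin 5	ATAACC	0.089
31	PC1 Polycomb heterochromatin	CTCAGG	0.065
31	PC1 Polycomb heterochromatin	GCTAGA	0.105
31	PC1 Polycomb heterochromatin	ATTTCT	0.153
31	PC1 Polycomb heterochromatin	GGCAAA	0.192
32	PC2 Weak polycomb	GTGCGG	0.086
32	PC2 Weak polycomb	GACCCC	0.16
32	PC2 Weak polycomb	GTCTTA	0.127
32	PC2 Weak polycomb	TCAAGA	0.055
33	PC3 Polycomb	ACTTAA	0.115
33	PC3 Polycomb	CGCAGT	0.103
33	PC3 Polycomb	CGATCA	0.12
33	PC3 Polycomb	AGGAGG	0.18
34	PC4 Bivalent stem cell enhancer	TTCGTG	0.189
34	PC4 Bivalent stem cell enhancer	CAGAGT	0.195
34	PC4 Bivalent stem cell enhancer	ACAGAT	0.056
34	PC4 Bivalent stem cell enhancer	TCCGGC	0.201
35	TF1 NANOG / FOXA1 binding	ACGGGG	0.119
35	TF1 NANOG / FOXA1 binding	GTTACG	0.222
35	TF1 NANOG / FOXA1 binding	GGTCCT	0.097
35	TF1 NANOG / FOXA1 binding	CAATAC	0.23
36	TF2 CEBPB binding	TGAGCA	0.084
36	TF2 CEBPB binding	CTTGTA	0.102
36	TF2 CEBPB binding	GAGCTA	0.19
36	TF2 CEBPB binding	TGTTCG	0.097
37	TF3 FOXA1 / AR / ESR1 binding	CCGGGC	0.115
37	TF3 FOXA1 / AR / ESR1 binding	TTGCCG	0.182
37	TF3 FOXA1 / AR / ESR1 binding	TCTAAC	0.23
37	TF3 FOXA1 / AR / ESR1 binding	CCATCT	0.142
38	TF4 OTX2 binding	TACAAA	0.249
38	TF4 OTX2 binding	ATTTCG	0.139
38	TF4 OTX2 binding	GAAGGC	0.051
38	TF4 OTX2 binding	TCGTAA	0.216
39	TF5 AR binding	GTATTC	0.234
39	TF5 AR binding	GGCTAG	0.153
39	TF5 AR binding	GGGGCC	0.103
39	TF5 AR binding	GGGAAA	0.15
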