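peptide	allele	ic50_nm	source
FPRKLYFL	HLA-B*42:01	4	nsfp1_truncation
FPRKLYFL	HLA-B*08:01	10	nsfp1_truncation
FPRKLYFL	HLA-A*32:07	16	nsfp1_truncation
FPRKLYFL	HLA-A*68:23	20	nsfp1_truncation
FPRKLYFL	HLA-B*44:01	24	nsfp1_truncation
FPRKLYFL	HLA-B*07:02	43	nsfp1_truncation
FPRKLYFL	HLA-C*14:02	51	nsfp1_truncation
FPRKLYFL	HLA-B*53:01	62	nsfp1_truncation
FPRKLYFL	HLA-C*08:02	70	nsfp1_truncation
FPRKLYFL	HLA-B*07:01	93	nsfp1_truncation
FPRKLYFL	HLA-B*15:02	146	nsfp1_truncation
FPRKLYFL	HLA-C*07:02	152	nsfp1_truncation
FPRKLYFL	HLA-A*32:15	169	nsfp1_truncation
FPRKLYFL	HLA-C*03:04	260	nsfp1_truncation
FPRKLYFL	HLA-C*03:03	279	nsfp1_truncation
KFPRKLYF	HLA-A*24:03	2	nsfp1_truncation
KFPRKLYF	HLA-A*68:23	10	nsfp1_truncation
KFPRKLYF	HLA-A*32:07	15	nsfp1_truncation
KFPRKLYF	HLA-C*14:02	16	nsfp1_truncation
KFPRKLYF	HLA-C*03:03	41	nsfp1_truncation
KFPRKLYF	HLA-B*15:02	53	nsfp1_truncation
KFPRKLYF	HLA-C*07:02	56	nsfp1_truncation
KFPRKLYF	HLA-A*32:15	71	nsfp1_truncation
KFPRKLYF	HLA-B*15:03	161	nsfp1_truncation
KFPRKLYF	HLA-A*23:01	203	nsfp1_truncation
KFPRKLYF	HLA-B*44:01	279	nsfp1_truncation
KFPRKLYF	HLA-A*24:01	407	nsfp1_truncation
KFPRKLYF	HLA-B*27:02	410	nsfp1_truncation
PKFPRKLY	HLA-C*07:02	75	nsfp1_truncation
KPKFPRKL	HLA-B*42:01	44	nsfp1_truncation
KPKFPRKL	HLA-C*07:02	50	nsfp1_truncation
KPKFPRKL	HLA-B*07:02	125	nsfp1_truncation
KPKFPRKL	HLA-B*07:01	326	nsfp1_truncation
KPKFPRKL	HLA-A*32:07	477	nsfp1_truncation
DIKPKFPR	HLA-A*33:01	7	nsfp1_truncation
DIKPKFPR	HLA-C*07:02	100	nsfp1_truncation
DIKPKFPR	HLA-A*68:23	127	nsfp1_truncation
DIKPKFPR	HLA-A*68:01	210	nsfp1_truncation
DIKPKFPR	HLA-A*32:07	362	nsfp1_truncation
PRKLYFLH	HLA-A*68:23	25	nsfp1_truncation
PRKLYFLH	HLA-C*14:02	35	nsfp1_truncation
PRKLYFLH	HLA-A*32:07	48	nsfp1_truncation
NDIKPKFP	HLA-B*44:01	40	nsfp1_truncation
NDIKPKFP	HLA-A*68:23	84	nsfp1_truncation
NDIKPKFP	HLA-A*32:07	115	nsfp1_truncation
NDIKPKFP	HLA-C*08:02	262	nsfp1_truncation
NDIKPKFP	HLA-C*07:02	271	nsfp1_truncation
NDIKPKFP	HLA-A*32:15	332	nsfp1_truncation
ENDIKPKF	HLA-C*07:02	39	nsfp1_truncation
ENDIKPKF	HLA-B*44:01	75	nsfp1_truncation
ENDIKPKF	HLA-C*08:02	81	nsfp1_truncation
ENDIKPKF	HLA-A*32:07	169	nsfp1_truncation
ENDIKPKF	HLA-A*68:23	203	nsfp1_truncation
LENDIKPK	HLA-A*68:23	250	nsfp1_truncation
LENDIKPK	HLA-C*07:02	316	nsfp1_truncation
IKPKFPRK	HLA-A*68:23	69	nsfp1_truncation
IKPKFPRK	HLA-C*07:02	124	nsfp1_truncation
IKPKFPRK	HLA-A*32:07	159	nsfp1_truncation
IKPKFPRK	HLA-A*30:01	260	nsfp1_truncation
MISNQNFQ	HLA-A*68:23	8	lrrc37a2_truncation
MISNQNFQ	HLA-A*32:07	32	lrrc37a2_truncation
MISNQNFQ	HLA-A*32:15	168	lrrc37a2_truncation
MISNQNFQ	HLA-C*03:03	492	lrrc37a2_truncation
ISNQNFQG	HLA-A*68:23	30	lrrc37a2_truncation
ISNQNFQG	HLA-A*32:07	59	lrrc37a2_truncation
ISNQNFQG	HLA-C*12:03	132	lrrc37a2_truncation
ISNQNFQG	HLA-A*32:15	209	lrrc37a2_truncation
SNQNFQGN	HLA-A*68:23	132	lrrc37a2_truncation
SNQNFQGN	HLA-A*32:07	156	lrrc37a2_truncation
NQNFQGNY	HLA-A*30:02	13	lrrc37a2_truncation
NQNFQGNY	HLA-A*68:23	94	lrrc37a2_truncation
NQNFQGNY	HLA-B*15:01	139	lrrc37a2_truncation
NQNFQGNY	HLA-A*32:07	141	lrrc37a2_truncation
NQNFQGNY	HLA-A*32:15	335	lrrc37a2_truncation
QNFQGNYI	HLA-A*68:23	23	lrrc37a2_truncation
QNFQGNYI	HLA-A*32:07	36	lrrc37a2_truncation
QNFQGNYI	HLA-A*32:15	160	lrrc37a2_truncation
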