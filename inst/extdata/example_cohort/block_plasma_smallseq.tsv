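sample_id	plasma_smallseq_f1	plasma_smallseq_f2	plasma_smallseq_f3	plasma_smallseq_f4	plasma_smallseq_f5	plasma_smallseq_f6	plasma_smallseq_f7	plasma_smallseq_f8	plasma_smallseq_f9	plasma_smallseq_f10	plasma_smallseq_f11	plasma_smallseq_f12	plasma_smallseq_f13	plasma_smallseq_f14	plasma_smallseq_f15	plasma_smallseq_f16	plasma_smallseq_f17	plasma_smallseq_f18	plasma_smallseq_f19	plasma_smallseq_f20	plasma_smallseq_f21	plasma_smallseq_f22	plasma_smallseq_f23	plasma_smallseq_f24	plasma_smallseq_f25	plasma_smallseq_f26	plasma_smallseq_f27	plasma_smallseq_f28	plasma_smallseq_f29	plasma_smallseq_f30	plasma_smallseq_f31	plasma_smallseq_f32	plasma_smallseq_f33	plasma_smallseq_f34	plasma_smallseq_f35	plasma_smallseq_f36	plasma_smallseq_f37	plasma_smallseq_f38	plasma_smallseq_f39	plasma_smallseq_f40	plasma_smallseq_f41	plasma_smallseq_f42	plasma_smallseq_f43	plasma_smallseq_f44	plasma_smallseq_f45	plasma_smallseq_f46	plasma_smallseq_f47	plasma_smallseq_f48	plasma_smallseq_f49	plasma_smallseq_f50
S001	2	0	24	68	6	0	11	2	1	15	2	3	15	5	11	1	4	10	0	144	6	34	2	0	2	17	7	3	1	4	8	17	0	21	19	6	3	17	3	2	36	1	0	8	0	3	0	0	3	0
S002	2	0	31	57	2	0	3	3	5	23	4	3	2	19	7	1	21	2	8	20	8	31	4	0	0	13	33	73	2	9	2	35	0	34	31	8	7	97	0	0	11	0	0	21	3	13	2	1	6	2
S003	1	0	11	12	4	0	5	5	0	2	6	3	0	18	11	0	5	3	3	32	14	9	1	2	0	15	1	2	1	2	0	2	0	15	6	2	5	9	0	1	5	0	0	3	4	6	0	0	2	0
S004	0	3	27	18	1	1	7	4	0	16	1	3	11	36	33	1	10	12	3	86	20	46	3	0	7	7	5	8	1	5	16	7	3	27	12	85	6	31	10	3	194	1	0	61	16	10	9	4	2	1
S005	1	1	9	6	2	0	4	5	0	3	3	3	5	5	2	0	8	2	1	28	16	20	2	0	0	2	4	8	1	1	8	3	0	3	8	23	0	13	2	0	33	2	0	7	1	12	1	1	13	0
S006	0	3	37	43	13	0	4	1	0	7	15	8	0	34	35	0	22	1	2	27	9	13	0	0	1	13	13	14	1	8	5	8	4	34	8	17	5	56	33	2	114	0	0	22	3	10	4	0	7	1
S007	2	10	50	57	33	4	21	17	3	40	30	35	11	17	42	3	67	16	5	124	73	163	2	3	4	154	84	170	1	7	4	63	3	186	28	10	19	179	8	10	21	1	6	17	19	15	4	4	4	2
S008	0	15	77	101	22	0	32	20	5	4	22	31	5	11	33	4	20	36	1	324	124	130	31	0	6	81	110	612	1	6	58	4	5	248	17	35	3	42	19	7	15	13	1	3	20	36	10	0	25	11
S009	6	7	109	59	13	1	9	2	1	34	11	0	2	27	4	3	13	4	2	0	36	33	17	1	1	10	5	139	3	5	4	13	0	123	16	9	8	37	13	1	39	0	0	28	3	5	5	2	1	0
S010	2	0	59	11	0	0	4	5	0	1	11	2	4	6	4	1	1	3	0	264	6	17	2	0	5	3	16	1	2	2	19	0	2	71	24	7	2	9	9	2	3	2	1	0	0	14	2	2	0	0
S011	3	7	113	50	9	0	5	8	3	38	17	13	14	16	40	0	2	2	3	78	34	5	1	1	4	30	52	112	0	4	18	27	1	52	21	72	3	118	10	2	17	3	0	29	17	28	24	0	3	2
S012	2	6	146	73	3	0	20	15	6	8	18	10	13	60	44	4	50	7	11	280	2	80	35	3	5	94	68	53	2	20	24	76	3	10	27	45	18	53	2	21	510	0	9	55	13	7	8	6	14	2
S013	2	2	25	9	10	0	2	8	1	5	7	4	2	3	2	0	13	1	5	3	11	63	14	0	1	25	2	229	1	6	4	30	9	39	12	2	10	28	15	0	9	14	0	5	15	14	2	1	4	1
S014	2	2	169	77	10	2	22	35	0	35	25	7	48	30	27	3	66	12	1	410	16	54	5	0	11	38	35	495	2	8	13	37	14	183	95	53	15	96	18	7	30	3	2	93	7	41	5	2	12	0
S015	1	1	51	27	0	0	5	4	10	6	21	3	8	34	9	2	42	4	0	63	22	43	3	1	1	12	31	73	0	6	27	1	3	129	10	23	8	43	30	1	13	2	1	10	4	20	12	3	3	0
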