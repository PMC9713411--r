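sample_id	pbmc_smallseq_f1	pbmc_smallseq_f2	pbmc_smallseq_f3	pbmc_smallseq_f4	pbmc_smallseq_f5	pbmc_smallseq_f6	pbmc_smallseq_f7	pbmc_smallseq_f8	pbmc_smallseq_f9	pbmc_smallseq_f10	pbmc_smallseq_f11	pbmc_smallseq_f12	pbmc_smallseq_f13	pbmc_smallseq_f14	pbmc_smallseq_f15	pbmc_smallseq_f16	pbmc_smallseq_f17	pbmc_smallseq_f18	pbmc_smallseq_f19	pbmc_smallseq_f20	pbmc_smallseq_f21	pbmc_smallseq_f22	pbmc_smallseq_f23	pbmc_smallseq_f24	pbmc_smallseq_f25	pbmc_smallseq_f26	pbmc_smallseq_f27	pbmc_smallseq_f28	pbmc_smallseq_f29	pbmc_smallseq_f30	pbmc_smallseq_f31	pbmc_smallseq_f32	pbmc_smallseq_f33	pbmc_smallseq_f34	pbmc_smallseq_f35	pbmc_smallseq_f36	pbmc_smallseq_f37	pbmc_smallseq_f38	pbmc_smallseq_f39	pbmc_smallseq_f40	pbmc_smallseq_f41	pbmc_smallseq_f42	pbmc_smallseq_f43	pbmc_smallseq_f44	pbmc_smallseq_f45	pbmc_smallseq_f46	pbmc_smallseq_f47	pbmc_smallseq_f48	pbmc_smallseq_f49	pbmc_smallseq_f50	pbmc_smallseq_f51	pbmc_smallseq_f52	pbmc_smallseq_f53	pbmc_smallseq_f54	pbmc_smallseq_f55	pbmc_smallseq_f56	pbmc_smallseq_f57	pbmc_smallseq_f58	pbmc_smallseq_f59	pbmc_smallseq_f60
S001	22	1	0	1	1	2	0	0	20	6	1	2	0	28	7	7	3	1	0	26	9	0	28	3	7	0	25	7	5	11	65	4	2	8	4	0	11	1	6	12	221	0	1	3	45	2	12	3	0	0	2	0	0	6	1	5	10	6	4	22
S002	29	0	0	5	9	1	0	1	8	6	1	2	0	4	15	16	22	8	6	29	16	0	50	2	4	1	41	0	18	7	65	41	5	28	8	1	7	0	3	114	37	1	3	13	204	0	13	3	1	2	1	2	3	1	0	7	24	33	5	27
S003	11	3	0	0	18	4	0	0	21	8	2	0	0	41	6	4	6	2	2	15	19	1	15	8	10	12	7	8	19	6	173	14	3	95	7	0	4	0	2	32	68	2	5	0	35	1	19	0	2	1	0	0	7	13	0	5	18	17	3	28
S004	7	0	2	9	4	2	0	5	19	0	1	17	0	243	11	7	61	8	7	1091	78	0	77	17	12	11	74	7	28	12	253	26	17	373	5	1	15	5	8	25	224	15	5	20	75	1	29	11	2	2	6	4	7	15	1	21	39	22	6	22
S005	33	7	7	12	61	9	0	4	5	14	0	27	1	72	12	22	14	2	18	322	9	0	36	7	69	32	13	12	27	4	23	37	5	232	33	3	7	3	47	20	78	6	17	11	82	0	24	7	5	8	8	6	2	6	12	20	80	62	1	24
S006	23	8	0	5	23	2	0	1	29	4	0	3	0	39	19	1	19	2	3	272	12	0	5	3	16	3	11	10	14	6	68	63	0	51	3	1	5	1	50	15	134	5	6	14	41	0	12	6	1	1	9	1	18	6	6	1	78	26	1	38
S007	8	6	2	7	68	1	0	3	18	20	0	0	0	113	11	6	10	3	14	93	13	0	16	7	23	7	38	5	19	4	221	11	13	157	0	1	13	3	8	45	56	2	2	1	28	2	7	12	5	0	7	0	6	1	0	18	14	60	3	10
S008	81	4	1	2	31	3	0	2	1	3	0	2	0	26	4	3	8	4	3	182	3	0	7	4	4	1	21	7	2	3	17	15	7	103	8	3	8	4	16	28	15	0	4	4	11	2	5	10	3	2	2	0	11	1	4	3	1	47	0	15
S009	28	1	0	7	22	4	1	3	13	24	2	5	0	155	13	14	15	15	9	135	67	0	82	5	4	8	119	10	8	15	199	21	16	90	27	0	6	1	15	75	6	1	2	6	31	2	2	24	5	0	3	1	6	0	0	16	10	22	4	14
S010	19	0	4	17	70	2	0	1	36	7	1	0	0	34	8	9	30	1	1	107	11	1	46	11	3	4	17	19	8	3	50	3	5	150	16	3	8	0	15	16	94	1	15	1	35	0	3	0	3	4	3	1	4	2	1	2	47	38	5	4
S011	24	3	0	2	24	7	0	0	8	6	0	0	0	34	12	0	0	1	3	82	35	1	11	2	5	4	22	1	1	4	109	9	5	86	8	2	2	1	2	4	67	2	2	10	31	0	11	6	2	0	4	2	0	6	1	7	10	7	1	14
S012	20	5	1	9	6	2	0	2	8	11	1	8	0	75	5	4	5	5	1	29	15	0	10	5	9	3	16	9	13	1	63	6	4	153	6	0	18	2	18	131	29	0	6	1	5	0	7	17	2	2	3	1	17	3	0	7	6	37	11	43
S013	64	4	2	30	19	3	0	0	32	9	1	23	0	239	40	1	22	6	2	132	83	1	74	5	14	3	98	26	35	8	501	41	26	164	36	1	30	1	66	143	143	2	7	1	35	1	59	28	0	13	24	9	17	5	11	23	31	45	10	26
S014	47	7	1	6	20	10	0	4	13	1	1	0	0	96	12	9	6	1	4	72	33	0	15	19	9	2	52	2	3	3	62	20	36	46	0	1	6	5	14	65	50	1	3	12	16	2	32	4	1	0	4	1	4	4	0	13	28	19	6	25
S015	3	1	2	3	6	1	0	0	7	7	0	0	0	27	19	1	1	1	0	9	8	0	9	6	7	3	25	3	4	3	84	18	8	11	4	0	3	1	18	9	10	0	7	0	6	0	11	5	0	1	5	1	0	10	0	5	27	12	2	7
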