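sample_id	csf_cells_smallseq_f1	csf_cells_smallseq_f2	csf_cells_smallseq_f3	csf_cells_smallseq_f4	csf_cells_smallseq_f5	csf_cells_smallseq_f6	csf_cells_smallseq_f7	csf_cells_smallseq_f8	csf_cells_smallseq_f9	csf_cells_smallseq_f10	csf_cells_smallseq_f11	csf_cells_smallseq_f12	csf_cells_smallseq_f13	csf_cells_smallseq_f14	csf_cells_smallseq_f15	csf_cells_smallseq_f16	csf_cells_smallseq_f17	csf_cells_smallseq_f18	csf_cells_smallseq_f19	csf_cells_smallseq_f20	csf_cells_smallseq_f21	csf_cells_smallseq_f22	csf_cells_smallseq_f23	csf_cells_smallseq_f24	csf_cells_smallseq_f25	csf_cells_smallseq_f26	csf_cells_smallseq_f27	csf_cells_smallseq_f28	csf_cells_smallseq_f29	csf_cells_smallseq_f30	csf_cells_smallseq_f31	csf_cells_smallseq_f32	csf_cells_smallseq_f33	csf_cells_smallseq_f34	csf_cells_smallseq_f35	csf_cells_smallseq_f36	csf_cells_smallseq_f37	csf_cells_smallseq_f38	csf_cells_smallseq_f39	csf_cells_smallseq_f40
S001	0	1	0	4	3	4	0	4	9	5	3	10	27	14	8	10	3	3	9	3	1	0	31	61	3	1	102	33	16	2	0	11	30	3	25	9	0	30	24	125
S002	2	4	2	0	1	2	0	2	3	0	5	1	2	15	0	18	0	2	15	11	1	2	97	6	3	6	47	5	3	0	1	3	13	18	1	3	1	8	2	30
S003	0	5	0	6	4	0	0	1	7	0	0	4	1	13	0	7	2	0	22	11	0	1	82	11	2	8	20	6	3	0	0	3	1	51	31	1	1	34	4	5
S004	0	3	0	5	2	2	0	7	7	11	4	4	23	43	25	18	1	1	24	2	2	3	341	25	0	16	90	95	4	0	11	4	13	84	17	6	0	8	37	110
S005	2	2	0	6	4	1	0	1	6	6	2	8	15	27	2	12	2	3	18	16	4	0	80	21	0	12	34	23	4	0	5	6	19	17	31	4	0	63	7	102
S006	2	2	5	3	8	3	0	2	4	0	7	2	19	18	3	9	6	0	29	4	0	1	40	13	0	20	16	34	7	0	3	1	9	32	38	5	0	41	21	65
S007	4	2	1	17	3	3	0	4	5	6	19	0	9	44	0	10	6	0	43	25	1	4	103	62	1	10	59	29	23	1	0	1	17	13	5	0	4	18	37	13
S008	2	21	5	10	7	1	1	10	24	2	24	11	6	34	7	43	5	1	56	3	1	0	128	41	0	42	15	4	15	2	10	2	19	35	39	12	17	54	34	12
S009	2	7	1	8	2	2	0	1	0	2	3	4	13	25	3	1	2	1	18	8	0	0	119	15	2	5	75	25	4	0	8	3	7	10	2	3	0	6	17	57
S010	0	3	0	2	10	2	0	5	1	4	6	0	6	24	13	10	4	1	8	23	1	0	94	61	5	9	28	6	1	0	6	5	30	104	28	1	7	96	6	33
S011	0	9	0	1	2	2	0	0	9	3	19	1	26	29	5	7	0	2	9	16	2	2	66	31	0	14	26	8	8	2	8	2	19	86	6	1	3	3	9	21
S012	3	0	0	5	3	0	0	3	8	0	5	2	41	23	4	6	9	1	30	18	2	0	48	18	1	1	12	25	3	0	1	3	10	21	15	0	1	59	6	31
S013	0	1	7	4	1	0	0	7	2	2	0	4	15	60	6	5	1	0	13	1	0	0	27	16	2	14	26	35	6	0	17	0	7	39	4	1	9	8	22	19
S014	0	7	3	0	1	0	0	9	14	2	8	4	12	62	4	21	3	3	42	18	10	1	21	21	0	52	95	24	25	2	3	1	2	80	17	0	1	25	12	30
S015	2	15	9	10	13	4	0	3	10	2	15	7	44	63	18	26	9	2	99	24	4	0	14	168	3	32	137	9	4	5	11	8	9	65	7	17	1	8	27	49
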