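sample_id	csf_free_mintmap_f1	csf_free_mintmap_f2	csf_free_mintmap_f3	csf_free_mintmap_f4	csf_free_mintmap_f5	csf_free_mintmap_f6	csf_free_mintmap_f7	csf_free_mintmap_f8	csf_free_mintmap_f9	csf_free_mintmap_f10	csf_free_mintmap_f11	csf_free_mintmap_f12	csf_free_mintmap_f13	csf_free_mintmap_f14	csf_free_mintmap_f15	csf_free_mintmap_f16	csf_free_mintmap_f17	csf_free_mintmap_f18	csf_free_mintmap_f19	csf_free_mintmap_f20	csf_free_mintmap_f21	csf_free_mintmap_f22	csf_free_mintmap_f23	csf_free_mintmap_f24	csf_free_mintmap_f25	csf_free_mintmap_f26	csf_free_mintmap_f27	csf_free_mintmap_f28	csf_free_mintmap_f29	csf_free_mintmap_f30	csf_free_mintmap_f31	csf_free_mintmap_f32	csf_free_mintmap_f33	csf_free_mintmap_f34	csf_free_mintmap_f35	csf_free_mintmap_f36	csf_free_mintmap_f37	csf_free_mintmap_f38	csf_free_mintmap_f39	csf_free_mintmap_f40
S001	0	76	8	2	73	12	1	0	1	132	35	7	674	2	4	112	38	2	98	37	1	465	7	1	17	27	3	20	4	3	56	4	2	8	0	46	7	4	180	64
S002	1	9	1	2	5	6	1	0	0	33	5	1	43	6	0	7	13	0	56	0	3	765	2	0	7	17	4	1	0	0	9	2	1	6	0	17	0	1	26	3
S003	1	9	2	1	29	3	0	0	1	24	0	2	161	6	0	8	19	1	84	3	7	381	2	1	4	3	1	28	9	0	4	2	1	3	1	20	3	7	68	13
S004	2	91	2	6	13	33	1	2	3	64	23	2	855	1	0	32	6	3	97	3	0	578	2	0	6	44	6	14	3	1	39	7	1	3	0	5	0	5	26	35
S005	0	3	0	0	3	8	0	0	0	22	4	1	168	1	1	9	2	0	10	11	1	472	1	0	5	4	6	11	0	1	7	2	2	1	0	0	1	1	18	5
S006	0	1	2	1	1	17	0	1	2	66	12	9	179	6	0	30	8	0	36	9	0	568	4	0	1	9	7	17	7	2	1	0	7	1	0	62	5	16	120	5
S007	5	114	6	7	17	19	1	4	1	89	51	14	191	14	1	13	15	0	14	3	7	1928	5	0	6	36	24	50	12	4	14	2	39	7	0	56	3	7	43	32
S008	0	24	0	4	22	9	0	0	1	31	9	15	11	15	2	54	95	0	7	9	6	396	5	2	10	17	127	13	8	2	32	7	45	1	0	40	6	21	121	12
S009	3	38	0	1	7	9	1	0	3	24	33	0	80	4	0	22	68	0	10	10	4	1293	10	1	3	9	7	21	7	3	93	1	11	10	0	35	16	37	365	55
S010	0	30	1	2	14	18	1	0	1	105	14	2	6	3	1	16	34	1	24	3	4	111	2	1	2	11	79	11	2	9	16	3	29	3	0	18	3	8	45	2
S011	0	60	7	4	16	14	0	1	0	325	31	1	134	4	2	50	71	0	117	18	3	1638	11	1	3	18	18	26	1	11	94	2	16	7	1	45	5	11	54	25
S012	0	3	4	1	31	36	1	0	1	27	5	3	240	1	1	31	15	1	79	5	1	1325	5	3	8	14	6	22	11	3	13	9	0	0	0	13	7	2	7	20
S013	3	21	8	1	30	4	3	0	2	91	15	17	32	14	1	15	55	2	80	2	4	1706	6	1	8	65	74	14	17	3	37	1	19	10	1	24	10	2	123	8
S014	3	17	6	3	11	32	0	1	0	55	28	12	65	13	1	29	16	1	23	2	0	472	1	1	0	21	24	12	5	3	23	0	36	5	1	4	3	11	254	18
S015	0	14	1	0	8	3	0	0	2	15	19	5	0	10	1	26	7	2	21	1	0	59	1	1	3	2	14	3	7	0	29	7	6	3	0	13	1	3	127	4
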