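breakdown	assay	category	count	total	reported_percent
source	smallseq	plasma	19	32	59.4
source	smallseq	csf_free	11	32	34.4
source	smallseq	csf_cells	2	32	6.3
source	mintmap	csf_cells	6	12	50.0
source	mintmap	csf_free	5	12	41.7
source	mintmap	plasma	1	12	8.3
trf_class	mintmap	i-tRF	4	12	33.3
trf_class	mintmap	5p-tRF	3	12	25.0
trf_class	mintmap	3p-tRF	4	12	33.3
trf_class	mintmap	3p-half	1	12	8.3
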