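source	assay	n_features
pbmc	smallseq	21615
pbmc	mintmap	3645
plasma	smallseq	1535
plasma	mintmap	323
csf_cells	smallseq	1638
csf_free	smallseq	818
csf_cells	mintmap	515
csf_free	mintmap	250
csf_cells	methylome	143013
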