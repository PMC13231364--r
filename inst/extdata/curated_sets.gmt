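AT2	synthetic placeholder: lung alveolar type II marker genes; replace with a curated list	SFTPB	SFTPC	SFTPA1	SFTPA2	SFTPD	NAPSA	LAMP3	PGC	SLC34A2	CTSH
EFFECTOR	synthetic placeholder: cytotoxic T/NK effector markers; replace with a curated list	GZMB	GZMA	GZMH	PRF1	GNLY	NKG7	KLRD1	FGFBP2	CST7	CTSW
MHC_II	synthetic placeholder: MHC class II antigen presentation; replace with a curated list	HLA-DRA	HLA-DRB1	HLA-DRB5	HLA-DQA1	HLA-DQB1	HLA-DQB2	HLA-DPA1	HLA-DPB1	HLA-DMA	HLA-DMB	CD74
MYELOID_IMMUNE_SUPPRESSION	synthetic placeholder: myeloid-mediated immune suppression; replace with a curated list	IL10	TGFB1	ARG1	IDO1	NOS2	CD274	LGALS9	VEGFA	PTGS2	MRC1
CHECKPOINT	synthetic placeholder: immune checkpoint molecules; replace with a curated list	PDCD1	CD274	PDCD1LG2	CTLA4	HAVCR2	LAG3	TIGIT	BTLA	VSIR	CD276
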