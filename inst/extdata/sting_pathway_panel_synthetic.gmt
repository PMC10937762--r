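STING_PATHWAY_CORE_25	synthetic stand-in panel of 25 core cGAS-STING pathway genes (curated from the canonical pathway literature; replaceable via read_gene_sets)	CGAS	STING1	TBK1	IRF3	IRF7	NFKB1	RELA	IKBKE	IKBKB	TREX1	IFI16	DDX41	TRAF3	TRAF6	TBKBP1	IFNB1	IFNA1	CXCL10	ISG15	IFIT1	IFIT3	MX1	OAS1	STAT1	ISG20
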