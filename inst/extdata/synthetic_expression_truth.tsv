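gene_id	role
gene_0001	regulon
gene_0002	regulon
gene_0003	background
gene_0004	regulon
gene_0005	background
gene_0006	background
gene_0007	background
gene_0008	background
gene_0009	regulon
gene_0010	background
gene_0011	background
gene_0012	regulon
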