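eicosanoid_synthesis	synthetic demo set	gene_0001	gene_0002	gene_0003	gene_0004
interleukin_signaling	synthetic demo set	gene_0005	gene_0006	gene_0007
gpcr_signaling	synthetic demo set	gene_0002	gene_0008	gene_0009	gene_0010	gene_0011
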