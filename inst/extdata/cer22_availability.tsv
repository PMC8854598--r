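# SNP ids available in all external datasets required for the two-sample MR
# (replication GWAS and the T2D outcome meta-analysis).  The strongest
# discovery signal (rs686548) is absent: it could not be looked up
# everywhere, so instrument selection must skip it.
snp
rs680379
rs168622
rs364585
rs4814176
rs3903703
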