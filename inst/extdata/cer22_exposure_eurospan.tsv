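# SNP-Cer22:0 associations, EUROSPAN replication meta-analysis (n = 4034),
# per-SD units.  Allele labels are SYNTHETIC placeholders encoding the
# published effect directions (opposite effect-allele coding to EPIC/FHSOC).
snp	effect_allele	other_allele	beta	se	p	n
rs680379	G	A	0.054	0.007	1.3e-13	4034
rs168622	G	A	0.054	0.007	1.2e-13	4034
rs364585	G	A	0.054	0.007	1.1e-13	4034
rs4814176	G	A	0.054	0.007	1.0e-13	4034
rs3903703	G	A	0.054	0.008	1.4e-12	4034
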