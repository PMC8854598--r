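# SNP-Cer22:0 associations, EPIC-Potsdam discovery GWAS (n = 1094), per-SD units.
# Allele labels are SYNTHETIC placeholders (the published table prints none);
# they are chosen so that effect directions across cohorts are encoded
# consistently: EPIC and FHSOC report the A allele, EUROSPAN the G allele.
snp	effect_allele	other_allele	beta	se	p	n
rs686548	A	G	-0.203	0.039	2.1e-07	1094
rs680379	A	G	-0.201	0.039	2.3e-07	1094
rs1321940	A	G	-0.201	0.039	2.4e-07	1094
rs4814175	A	G	-0.200	0.039	3.2e-07	1094
rs4814176	A	G	-0.200	0.039	3.2e-07	1094
rs168622	A	G	-0.197	0.039	4.1e-07	1094
rs364585	A	G	-0.197	0.039	4.2e-07	1094
rs3903703	A	G	-0.198	0.040	8.7e-07	1094
rs780094	A	G	-0.193	0.040	1.6e-06	1094
rs780093	A	G	-0.188	0.040	2.9e-06	1094
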