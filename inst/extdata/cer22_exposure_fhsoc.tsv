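# SNP-Cer22:0 associations, Framingham Heart Study Offspring Cohort
# (n = 2217), per-microM units.  Allele labels are SYNTHETIC placeholders
# encoding the published effect directions (same coding as EPIC-Potsdam).
snp	effect_allele	other_allele	beta	se	p	n
rs686548	A	G	-0.031	0.005	6.8e-11	2217
rs680379	A	G	-0.031	0.005	4.0e-11	2217
rs1321940	A	G	-0.031	0.005	3.5e-11	2217
rs4814175	A	G	-0.031	0.005	2.8e-11	2217
rs4814176	A	G	-0.031	0.005	3.6e-11	2217
rs168622	A	G	-0.031	0.005	3.0e-11	2217
rs364585	A	G	-0.031	0.005	3.1e-11	2217
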