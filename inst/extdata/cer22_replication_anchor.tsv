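# Published two-sample MR anchor: the EUROSPAN-exposure Wald ratio for the
# Cer22:0 -> T2D analysis (outcome: DIAGRAM T2D meta-analysis).  The
# SNP-outcome effect itself is not published; it is implied by this row as
# beta_outcome = wr * beta_exposure and se_outcome = se * beta_exposure on
# the EUROSPAN allele coding.
cohort	snp	wr	se	p
EUROSPAN	rs680379	0.259	0.120	0.031
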