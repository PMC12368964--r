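chrom	label	start	end	haplotype
chr1	A	11296105	11302315	derived
chr1	B	19180947	19187825	derived
chr1	C	28333982	28336075	derived
chr2	A	21848272	21858616	derived
chr2	B	26151340	26163504	derived
chr7	A	16838295	16871460	derived
chr7	B	26338531	26410445	derived
chr12	A	638394	646752	derived
chr12	B	13659852	13660483	derived
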