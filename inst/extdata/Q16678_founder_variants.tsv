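# Published per-variant pathogenicity scores for four CYP1B1 (UniProt Q16678)
# founder mutations, in the UniProt-substitution TSV dialect.
uniprot_id	protein_variant	am_pathogenicity	am_class
Q16678	G61E	0.9839	likely_pathogenic
Q16678	E387K	0.9508	likely_pathogenic
Q16678	R390H	0.8207	likely_pathogenic
Q16678	V320L	0.381	ambiguous
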