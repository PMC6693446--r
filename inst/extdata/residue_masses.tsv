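# iturityper residue table v1: amino-acid residues occurring in the iturinic
# heptapeptides (plus Gly, used as a non-family sentinel in examples).
# Monoisotopic residue masses are computed at load time from the formulas.
three_letter	one_letter	formula
Asn	N	C4H6N2O2
Tyr	Y	C9H9NO2
Gln	Q	C5H8N2O2
Pro	P	C5H7NO
Ser	S	C3H5NO2
Thr	T	C4H7NO2
Glu	E	C5H7NO3
Gly	G	C2H3NO
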