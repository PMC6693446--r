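# iturityper ituB primer sets v1 (B. velezensis diagnostic assay).
# All three sets share the forward primer, sited on the conserved AA#3 module;
# reverse primers sit on the variable AA#4 module of each cluster type.
name	forward	reverse	expected_band	target_compound
ituB-iturin	CACGAACAGACAAAACA	TGCGCAAAGCATCGT	1113	iturin A
ituB-bacD	CACGAACAGACAAAACA	CTTGCGGCGTTTGTG	732	bacillomycin D
ituB-bacL	CACGAACAGACAAAACA	GGTCGCTCCTGAATCT	1016	bacillomycin L
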