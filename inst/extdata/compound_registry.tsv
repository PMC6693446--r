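# iturityper compound registry v1: the six iturinic lipopeptides.
# Positions aa1-aa3 are the conserved Asn-Tyr-Asn head; aa4-aa7 are the
# variable positions that define the chemotype. proline_position is empty for
# bacillomycin L, the one family member without a proline.
name	aa1	aa2	aa3	aa4	aa5	aa6	aa7	proline_position	producer_species
iturin A	Asn	Tyr	Asn	Gln	Pro	Asn	Ser	5	B. velezensis;B. amyloliquefaciens;B. siamensis;B. nakamurai
mycosubtilin	Asn	Tyr	Asn	Gln	Pro	Ser	Asn	5	B. subtilis subsp. spizizenii;B. atrophaeus
bacillomycin D	Asn	Tyr	Asn	Pro	Glu	Ser	Thr	4	B. velezensis;B. siamensis
bacillomycin F	Asn	Tyr	Asn	Gln	Pro	Asn	Thr	5	B. subtilis subsp. inaquosorum
bacillomycin L	Asn	Tyr	Asn	Ser	Glu	Ser	Thr		B. velezensis
mojavensin A	Asn	Tyr	Asn	Gln	Pro	Asn	Asn	5	B. halotolerans;B. swezeyi
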