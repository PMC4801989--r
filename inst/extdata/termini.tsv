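# pepkit predefined termini, version 1.0
# delta = formula added to the bare (dehydrated) chain end.
# unmodified N (+H) with acid C (+OH) reconstitutes the free peptide (chain + H2O)
name	end	delta	predefined
unmodified	N	H	TRUE
acetyl	N	C2H3O	TRUE
formyl	N	CHO	TRUE
acid	C	HO	TRUE
amide	C	H2N	TRUE
methyl ester	C	CH3O	TRUE
ethyl 3-mercaptopropionate thioester	C	C5H9O2S	TRUE
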