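# pepkit peptoid building-block table, version 1.0
# N-substituted glycine residues: formula = C2H2NO backbone + N-substituent
code	name	formula
Nme	N-methylglycine (sarcosine)	C3H5NO
Net	N-ethylglycine	C4H7NO
Npr	N-propylglycine	C5H9NO
Nbu	N-butylglycine	C6H11NO
Npm	N-benzylglycine	C9H9NO
Npe	N-(2-phenylethyl)glycine	C10H11NO
Nspe	N-((S)-1-phenylethyl)glycine	C10H11NO
Nae	N-(2-aminoethyl)glycine	C4H8N2O
Nab	N-(4-aminobutyl)glycine	C6H12N2O
Nce	N-(2-carboxyethyl)glycine	C5H7NO3
Nhe	N-(2-hydroxyethyl)glycine	C4H7NO2
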