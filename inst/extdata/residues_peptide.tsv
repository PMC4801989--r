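# pepkit peptide residue table, version 1.0
# formula = chain-incorporated (dehydrated) composition; termini supply end groups
# ionizable refers to a side-chain group id in pka.tsv; chromophore feeds the 280 nm calculator
code	name	formula	canonical	ionizable	chromophore
A	alanine	C3H5NO	TRUE	-	-
R	arginine	C6H12N4O	TRUE	Arg	-
N	asparagine	C4H6N2O2	TRUE	-	-
D	aspartate	C4H5NO3	TRUE	Asp	-
C	cysteine	C3H5NOS	TRUE	Cys	Cys
E	glutamate	C5H7NO3	TRUE	Glu	-
Q	glutamine	C5H8N2O2	TRUE	-	-
G	glycine	C2H3NO	TRUE	-	-
H	histidine	C6H7N3O	TRUE	His	-
I	isoleucine	C6H11NO	TRUE	-	-
L	leucine	C6H11NO	TRUE	-	-
K	lysine	C6H12N2O	TRUE	Lys	-
M	methionine	C5H9NOS	TRUE	-	-
F	phenylalanine	C9H9NO	TRUE	-	-
P	proline	C5H7NO	TRUE	-	-
S	serine	C3H5NO2	TRUE	-	-
T	threonine	C4H7NO2	TRUE	-	-
W	tryptophan	C11H10N2O	TRUE	-	Trp
Y	tyrosine	C9H9NO2	TRUE	Tyr	Tyr
V	valine	C5H9NO	TRUE	-	-
pS	phosphoserine	C3H6NO5P	FALSE	-	-
pT	phosphothreonine	C4H8NO5P	FALSE	-	-
pY	phosphotyrosine	C9H10NO5P	FALSE	-	-
Nle	norleucine	C6H11NO	FALSE	-	-
Orn	ornithine	C5H10N2O	FALSE	-	-
Cit	citrulline	C6H11N3O2	FALSE	-	-
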