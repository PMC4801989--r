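# pepkit pKa set, version 1.0 (IPC_peptide values, Kozlowski 2016)
# sign: -1 = acidic group (deprotonation gives -1), +1 = basic group
group	pka	sign
Nterm	9.564	1
Cterm	2.383	-1
Asp	3.887	-1
Glu	4.317	-1
Cys	8.297	-1
Tyr	10.071	-1
His	6.018	1
Lys	10.517	1
Arg	12.503	1
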