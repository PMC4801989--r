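# pepkit element mass table, version 1.0
# mass of the single most abundant isotope, in u (AME2020 rounded to 6 dp)
symbol	mass
H	1.007825
C	12.000000
N	14.003074
O	15.994915
S	31.972071
P	30.973762
Na	22.989769
K	38.963707
F	18.998403
Cl	34.968853
Br	78.918338
I	126.904473
Se	79.916522
Fe	55.934936
Zn	63.929142
Cu	62.929598
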