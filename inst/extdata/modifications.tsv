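# pepkit modification table, version 1.0
# delta = plus formula minus the minus formula, applied to the whole species.
# metals follow the salt-form convention (+metal -H); protecting groups replace
# one proton on the licensed side chain.  sites: residue codes (or Nterm) that
# license the modification; '-' = unrestricted (metal adducts).
name	kind	plus	minus	sites	max_per_site
Na	metal	Na	H	-	1
K	metal	K	H	-	1
Pbf	protecting_group	C13H17O3S	H	R	1
Boc	protecting_group	C5H9O2	H	K,W,Nterm	1
tBu	protecting_group	C4H9	H	S,T,Y,D,E	1
Trt	protecting_group	C19H15	H	C,H,N,Q	1
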