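name	residues	formula	h_exch	note
Pro	Pro	C4H8N	1	
Hyp	Hyp	C4H8NO	2	N-H and O-H exchangeable
Val	Val	C4H10N	2	
Leu/Ile	Leu/Ile	C5H12N	2	Leu and Ile are isomeric; one species
Phe	Phe	C8H10N	2	
Gly	Gly	CH4N	2	m/z 30, below the usual m/z 50 low cutoff
Ala	Ala	C2H6N	2	m/z 44, below the usual m/z 50 low cutoff
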