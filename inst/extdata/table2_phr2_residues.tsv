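# Contact-shell positions of the reference cyanobacterial photolyase at which at
# least one haloarchaeal Phr2 differs, with the residue observed in each strain.
# Positions use the reference (SEL) numbering that excludes the initiator Met.
# interaction: ligand class assigned to the position in the published table.
# BOL4-2 and GSL-19 duplicate the NRC-1 column per the published footnote
# ("NRC-1 residues are the same as BOL4-2 and GSL-19").
# Known provenance caveats, carried as-is: position 282 is labelled DNA here but
# is discussed as FAD-interacting in the accompanying text; BOL3-1 differs from
# NRC-1 at position 385 although the text calls BOL3-1 free of key-residue
# substitutions.
pos	interaction	SEL	NRC-1	JOR-1	Hla	BOL3-1	BOL5-1	BOL6-1	BOL4-2	GSL-19
50	HDF	R	R	R	R	R	V	R	R	R
139	DNA	S	T	T	T	T	T	P	T	T
144	DNA	P	P	P	P	P	H	H	P	P
147	DNA	V	V	V	V	V	D	V	V	V
148	DNA	Y	Y	Y	Y	Y	F	F	Y	Y
149	DNA	G	T	T	S	T	S	S	T	T
150	DNA	P	Y	Y	Y	Y	D	Y	Y	Y
242	FAD	L	L	V	M	L	L	L	L	L
279	FAD	W	F	F	Y	F	F	F	F	F
282	DNA	E	Q	Q	Q	Q	R	Q	Q	Q
384	FAD	A	N	N	N	N	H	N	N	N
385	FAD	N	D	D	D	N	A	D	D	D
398	DNA	D	D	D	D	D	N	D	D	D
413	DNA	K	R	D	R	R	T	E	R	R
460	DNA	Q	R	R	R	R	H	R	R	R
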