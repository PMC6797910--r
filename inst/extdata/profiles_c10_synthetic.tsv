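id	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
hydrophobic	0.185	0.004999999999999999	0.004999999999999999	0.004999999999999999	0.004999999999999999	0.004999999999999999	0.004999999999999999	0.185	0.004999999999999999	0.185	0.185	0.004999999999999999	0.004999999999999999	0.004999999999999999	0.004999999999999999	0.004999999999999999	0.004999999999999999	0.185	0.004999999999999999	0.004999999999999999
aromatic	0.005	0.005	0.005	0.005	0.305	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.305	0.305
basic	0.005	0.005	0.005	0.005	0.005	0.005	0.305	0.005	0.305	0.005	0.005	0.005	0.005	0.005	0.305	0.005	0.005	0.005	0.005	0.005
acidic	0.005	0.005	0.455	0.455	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005
amide	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.455	0.005	0.455	0.005	0.005	0.005	0.005	0.005	0.005
hydroxyl	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.455	0.455	0.005	0.005	0.005
tiny	0.305	0.005	0.005	0.005	0.005	0.305	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.305	0.005	0.005	0.005	0.005
turn	0.005	0.005	0.005	0.005	0.005	0.305	0.005	0.005	0.005	0.005	0.005	0.305	0.305	0.005	0.005	0.005	0.005	0.005	0.005	0.005
thiol	0.305	0.305	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.305	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005	0.005
charged	0.005	0.005	0.23	0.23	0.005	0.005	0.005	0.005	0.23	0.005	0.005	0.005	0.005	0.005	0.23	0.005	0.005	0.005	0.005	0.005
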