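ref_id	pos	ref_base	strain_1	strain_2
ref_1	78	A	G	A
ref_1	158	G	G	T
ref_1	259	A	C	A
ref_1	378	C	A	C
ref_1	455	A	A	G
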