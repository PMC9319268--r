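position	characteristic_of	A	B	C	M
39	A	T	-	-	-
122	A	A	G	G	G
130	A	A	G	G	A
145	A	G	A	A	A
146	A	A	T	T	T
166	M	A	A	A	G
196	M	A	A	A	G
200	A	T	C	C	C
210	M	A	A	A	G
269	C	G	G	A	G
466	C	A	A	C	A
475	C	T	T	-	T
494	M	C/T	C/T	C/T	A
518	M	T	T	T	G
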