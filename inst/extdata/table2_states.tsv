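sample_id	country	species	printed_type	39	122	130	145	146	166	196	200	210	269	466	475	494	518	accession	is_haploid
IE965	Mexico	A. macrochlamys	MM	-	G	A	A	T	G	G	C	G	G	A	T	A	G	KY114573	FALSE
IE973	Mexico	A. macrochlamys	MM	-	G	A	A	T	G	G	C	G	G	A	T	A	G	KY114574	FALSE
CA1110	Mexico	A. macrochlamys	MM	-	G	A	A	T	G	G	C	G	G	A	T	A	G	KY704307	FALSE
IE903	Mexico	A. macrochlamys	MM	-	G	A	A	T	G	G	C	G	G	A	T	A	G	ON332803	FALSE
IE904	Mexico	A. macrochlamys	MM	-	G	A	A	T	G	G	C	G	G	A	T	A	G	ON332804	FALSE
IE4012	Mexico	A. macrochlamys	MM	-	G	A	A	T	G	G	C	G	G	A	T	A	G	ON332805	FALSE
LD201901	Mexico	A. macrochlamys	MM	-	G	A	A	T	G	G	C	G	G	A	T	A	G	ON332799	FALSE
LD201927	Mexico	A. macrochlamys	MM	-	G	A	A	T	G	G	C	G	G	A	T	A	G	ON332800	FALSE
LD201934	Mexico	A. macrochlamys	MM	-	G	A	A	T	G	G	C	G	G	A	T	A	G	ON332801	FALSE
LD201938	Mexico	A. macrochlamys	MM	-	G	A	A	T	G	G	C	G	G	A	T	A	G	ON332802	FALSE
JBSD126480	Dominican Republic	A. macrochlamys	MM	-	G	A	A	T	G	G	C	G	G	A	T	A	G	ON332793	FALSE
JBSD126482	Dominican Republic	A. macrochlamys	MM	-	G	A	A	T	G	G	C	G	G	A	T	A	G	ON332794	FALSE
JBSD126483	Dominican Republic	A. macrochlamys	MM	-	G	A	A	T	G	G	C	G	G	A	T	A	G	ON332795	FALSE
JBSD126484	Dominican Republic	A. macrochlamys	MM	-	G	A	A	T	G	G	C	G	G	A	T	A	G	ON332796	FALSE
JBSD130773	Dominican Republic	A. macrochlamys	MM	-	G	A	A	T	G	G	C	G	G	A	T	A	G	ON332797	FALSE
JBSD130774	Dominican Republic	A. macrochlamys	MM	-	G	A	A	T	G	G	C	G	G	A	T	A	G	ON332798	FALSE
ARB1353	USA	A. macrochlamys	MM	-	G	A	A	T	G	G	C	G	G	A	T	A	G	KY704305	FALSE
F2285	Martinique	A. subrufescens	AA	T	A	A	G	A	A	A	T	A	G	A	T	Y	T	JF797201	FALSE
LAPAM13	Dominican Republic	A. subrufescens	AA	T	A	A	G	A	A	A	T	A	G	A	T	T	T	MF511115	FALSE
LAPAM37	Dominican Republic	A. subrufescens	AA	T	A	A	G	A	A	A	T	A	G	A	T	C	T	MF511128	FALSE
LAPAM77	Dominican Republic	A. subrufescens	AA	T	A	A	G	A	A	A	T	A	G	A	T	C	T	ON332807	FALSE
LAPAM78	Dominican Republic	A. subrufescens	AA	T	A	A	G	A	A	A	T	A	G	A	T	Y	T	ON332808	FALSE
LAPAM100	Dominican Republic	A. subrufescens	AA	T	A	A	G	A	A	A	T	A	G	A	T	Y	T	ON332809	FALSE
LAPAM101	Dominican Republic	A. subrufescens	AA	T	A	A	G	A	A	A	T	A	G	A	T	C	T	ON332810	FALSE
LAPAM103	Dominican Republic	A. subrufescens	AA	T	A	A	G	A	A	A	T	A	G	A	T	C	T	ON332811	FALSE
CA603A	Mexico	A. subrufescens	A	T	A	A	G	A	A	A	T	A	G	A	T	C	T	KY704306	TRUE
WC837-S43	Brazil	A. subrufescens	A	T	A	A	G	A	A	A	T	A	G	A	T	C	T	KJ541797	TRUE
CA864A	France	A. subrufescens	A	T	A	A	G	A	A	A	T	A	G	A	T	T	T	KU557349	TRUE
CA487-C5	France	A. subrufescens	A	T	A	A	G	A	A	A	T	A	G	A	T	C	T	KU557352	TRUE
CA603B	Mexico	A. subrufescens	B	-	G	G	A	T	A	A	C	A	G	A	T	C	T	KY704306	TRUE
L0341732	UK	A. subrufescens	BB	-	G	G	A	T	A	A	C	A	G	A	T	C	T	AY818649	FALSE
IE913	Mexico	A. subrufescens	BB	-	G	G	A	T	A	A	C	A	G	A	T	C	T	KY114572	FALSE
LAPAM12	Dominican Republic	A. subrufescens	BB	-	G	G	A	T	A	A	C	A	G	A	T	C	T	MF511114	FALSE
WC837-S04	Brazil	A. subrufescens	B	-	G	G	A	T	A	A	C	A	G	A	T	C	T	KJ541796	TRUE
CA864B	France	A. subrufescens	B	-	G	G	A	T	A	A	C	A	G	A	T	C	T	KU557349	TRUE
CA487-C6	France	A. subrufescens	B	-	G	G	A	T	A	A	C	A	G	A	T	C	T	KU557353	TRUE
CA487-C2	France	A. subrufescens	C	-	G	G	A	T	A	A	C	A	A	C	-	C	T	KU557351	TRUE
GY128883	China	A. subrufescens	CC	-	G	G	A	T	A	A	C	A	A	C	-	C	T	KJ755634	FALSE
GY133048	China	A. subrufescens	CC	-	G	G	A	T	A	A	C	A	A	C	-	C	T	KJ755635	FALSE
GY121118	China	A. subrufescens	CC	-	G	G	A	T	A	A	C	A	A	C	-	C	T	KJ755633	FALSE
GY128956	China	A. subrufescens	CC	-	G	G	A	T	A	A	C	A	A	C	-	C	T	KJ755632	FALSE
XHW1614	China	A. subrufescens	CC	-	G	G	A	T	A	A	C	A	A	C	-	C	T	KJ755636	FALSE
ZRL2036	Thailand	A. subrufescens	CC	-	G	G	A	T	A	A	C	A	A	C	-	C	T	KU557345	FALSE
ZRL2134	Thailand	A. subrufescens	CC	-	G	G	A	T	A	A	C	A	A	C	-	C	T	KU557346	FALSE
ZRL20130601	China	A. subrufescens	CC	-	G	G	A	T	A	A	C	A	A	C	-	C	T	MK617873	FALSE
VM098	Iran	A. subrufescens	CC	-	G	G	A	T	A	A	C	A	A	C	-	C	T	KT983412	FALSE
NT001	Thailand	A. subrufescens	CC	-	G	G	A	T	A	A	C	A	A	C	-	C	T	KU557347	FALSE
CA935	Thailand	A. subrufescens	CC	-	G	G	A	T	A	A	C	A	A	C	-	C	T	KU557348	FALSE
CA918	Thailand	A. subrufescens	CC	-	G	G	A	T	A	A	C	A	A	C	-	C	T	KJ541798	FALSE
NTF67	Thailand	A. subrufescens	CC	-	G	G	A	T	A	A	C	A	A	C	-	C	T	JF514529	FALSE
DEH513	Hawaii	A. subrufescens	CC	-	G	G	A	T	A	A	C	A	A	C	-	C	T	AY818646	FALSE
DEH1073	Hawaii	A. subrufescens	CC	-	G	G	A	T	A	A	C	A	A	C	-	C	T	AY818647	FALSE
KRP070	Hawaii	A. subrufescens	CC	-	G	G	A	T	A	A	C	A	A	C	-	C	T	AY818648	FALSE
CA487	France	A. subrufescens	ABC	T/-	R	R	R	W	A	A	Y	A	R	M	T/-	C	T	KU557351;KU557352;KU557353	FALSE
CA603	Mexico	A. subrufescens	AB	T/-	R	R	R	W	A	A	Y	A	G	A	T	C	T	KY704306	FALSE
LD201903	Mexico	A. subrufescens	AB	T	R	R	A	T	A	A	Y	A	G	A	T	C	T	ON332806	FALSE
LAPAM11	Dominican Republic	A. subrufescens	AB	T	R	R	R	W	A	A	Y	A	G	A	T	Y	T	MF511113	FALSE
WC837	Brazil	A. subrufescens	AB	T/-	R	R	R	W	A	A	Y	A	G	A	T	C	T	KU557350	FALSE
CA864	France	A. subrufescens	AB	T/-	R	R	R	W	A	A	Y	A	G	A	T	Y	T	KU557349	FALSE
Fragment 10	USA	A. subrufescens	(AB)	T/-	R	R	R	W	A	A	Y	A	G	A	T	C	T	EU071699	FALSE
SBRF	USA	A. subrufescens	(AB)	T/-	R	R	R	W	A	A	Y	A	G	A	T	C	T	AY818656	FALSE
ZRL2012722	China	A. subrufescens	(aB)	-	A	G	A	T	A	A	C	A	G	A	-	C	T	KT951383	FALSE
ZRL20140153	China	A. subrufescens	(aB)	-	A	G	A	T	A	A	C	A	G	A	-	C	T	MK617874	FALSE
978	Brazil	A. subrufescens	(aB)	-	G	G	R	T	A	A	C	A	G	A	T	C	T	AY818650	FALSE
GY129365	China	A. subrufescens	(bC)	-	G	G	A	T	A	A	C	A	R	M	-	C	T	KJ755631	FALSE
ZRL20140275	China	A. subrufescens	(bC)	-	G	G	A	T	A	A	C	A	G	A	-	C	T	MK617876	FALSE
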