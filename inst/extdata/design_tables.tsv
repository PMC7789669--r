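category	entry	entry_type	pfam	n_domains	source
nitrogen metabolism	ArgI	gene	PF00491	1	PDC
nitrogen metabolism	SpeB	gene	PF00491	1	PDC
nitrogen metabolism	HutG	gene	PF00491	1	PDC
nitrogen metabolism	Glutaminase	gene	PF04960	1	PDC,T
nitrogen metabolism	FocA	gene	PF01226	1	PDC,T
nitrogen metabolism	PucR	gene	PF13556	1	PDC,T
nitrogen metabolism	NifS	gene	PF01458	1	PDC,T
nitrogen metabolism	NifU	gene	PF01458	1	PDC,T
nitrogen metabolism	RnfH	gene	PF03658	1	PDC,T
nitrogen metabolism	RnfNqr	gene	PF02508	1	PDC,T
nitrogen metabolism	NMO	gene	PF03060	1	PDC,T
nitrogen metabolism	AnsB	gene	PF06089	1	PDC,T
nitrogen metabolism	DauB	gene	PF02423	1	PDC,T
nitrogen metabolism	DauA	gene	PF01266	1	PDC,T
nitrogen metabolism	DauR	gene	PF08348	1	PDC,T
nitrogen metabolism	NarK1	gene	PF07690	1	PDC,T
nitrogen metabolism	NarK2	gene	PF07690	1	PDC,T
nitrogen metabolism	NarG	gene	PF14710;PF00384;PF01568	3	PDC,T
nitrogen metabolism	NarH	gene	PF13247;PF14711	2	PDC,T
nitrogen metabolism	NarJ	gene	PF02613	1	PDC,T
nitrogen metabolism	NarI	gene	PF02665	1	PDC,T
nitrogen metabolism	NarX	gene	PF02518;PF00672;PF07730;PF13675	4	PDC,T
nitrogen metabolism	NarL	gene	PF00072;PF00196	2	PDC,T
nitrogen metabolism	NirJ	gene	PF04055	1	PDC,T
nitrogen metabolism	NirF	gene	PF02239	1	PDC,T
nitrogen metabolism	NirL	gene	NA	1	PDC,T
nitrogen metabolism	NirQ	gene	PF07728;PF08406	2	PDC,T
nitrogen metabolism	NirM	gene	PF13442	1	PDC,T
nitrogen metabolism	NirS	gene	PF13442;PF02239	2	PDC,T
nitrogen metabolism	MoaA1	gene	PF00994;PF03453	2	PDC
nitrogen metabolism	MoaB1	gene	PF00994	1	PDC
nitrogen metabolism	NorB	gene	PF00034	1	PDC,T
nitrogen metabolism	NorC	gene	PF00115	1	PDC,T
nitrogen metabolism	NorD	gene	PF00092	1	PDC,T
nitrogen metabolism	NosR	gene	PF04205	1	PDC,T
hydrogenases	NiFeHyd	gene	PF14720	1	PDC
hydrogenases	HupF/HypC	gene	PF01455	1	PDC
hydrogenases	HycI	gene	PF01750	1	PDC
hydrogenases	HypA	gene	PF01924	1	PDC
hydrogenases	HupH	gene	PF04809	1	PDC
hydrogenases	HyaE	gene	PF07449	1	PDC
hydrogenases	HybE	gene	PF11939	1	PDC
hydrogenases	HypA2	gene	PF01155	1	PDC
hydrogenases	HupE/UreJ	gene	PF04955	1	PDC
cytochrome C	CytC552	gene	PF02335	1	PDC
pyrimidine & amino acid biosynthesis	PyrK-PyrD B	gene	NA	2	GSM
pyrimidine & amino acid biosynthesis	NrdD-NrdG	gene	NA	2	GSM
pyrimidine & amino acid biosynthesis	DNR	gene	PF00027;PF13545	2	PDC
pyrimidine & amino acid biosynthesis	vitamin B12	vitamin	NA	0	PDC,GSM
pyrimidine & amino acid biosynthesis	vitamin B6	vitamin	NA	0	GSM
pyrimidine & amino acid biosynthesis	vitamin K2	vitamin	NA	0	PDC,GSM
ATP generation	AckA	gene	NA	1	PDC,GSM
unknown function	DUF1924	domain	PF09086	1	PDC
unknown function	DUF1588	domain	PF07627	1	PDC
unknown function	DUF1587	domain	PF07626	1	PDC
unknown function	DUF1592	domain	PF07631	1	PDC
unknown function	DUF1595	domain	PF07637	1	PDC
unknown function	DUF2459	domain	PF09601	1	PDC
unknown function	DUF3865	domain	PF12981	1	PDC
unknown function	RyR	domain	PF02026	1	PDC
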