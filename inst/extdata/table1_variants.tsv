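gene	variant	grch38_location	cdna	protein	condition	clinical_significance	paralog_annotation
KMT2C	R4763Q	7:152,144,768	c.14288 G > A	p.Arg4763Gln	NP	VUS	-
KMT2C	E4792D	7:152,139,759	c.14376 G > C	p.Glu4792Asp	Kleefstra syndrome 2	VUS	-
KMT2C	G4802R	7:152,139,731	c.14404 G > A	p.Gly4802Arg	NP	VUS	-
KMT2C	I4805V	7:152,139,722	c.14413A > G	p.Ile4805Val	NP	VUS	-
KMT2C	E4808K	7:152,139,713	c.14422 G > A	p.Glu4808Lys	NP	VUS	-
KMT2C	R4828H	7:152,139,237	c.14483 G > A	p.Arg4828His	NP	VUS	-
KMT2C	C4851Y	7:152,138,887	c.14552 G > A	p.Cys4851Tyr	NP	VUS	-
KMT2C	N4854D	7:152,138,879	c.14560A > G	p.Asn4854Asp	NP	VUS	-
KMT2C	V4860A	7:152,138,860	c.14579 T > C	p.Val4860Ala	NP	VUS	-
KMT2C	Y4884C	7:152,136,917	c.14651A > G	p.Tyr4884Cys	NP	VUS	-
KMT2C	F4890Y	7:152,136,899	c.14669 T > A	p.Phe4890Tyr	NP	VUS	-
KMT2D	Q5387R	12:49,022,768	c.16160A > G	p.Gln5387Arg	NP	VUS	Q4761R
KMT2D	S5404C	12:49,022,717	c.16211 C > G	p.Ser5404Cys	Kabuki syndrome 1	VUS	S4778C
KMT2D	R5405H	12:49,022,714	c.16214 G > A	p.Arg5405His	NP	Likely benign	R4779H
KMT2D	V5423F	12:49,022,661	c.16267 G > T	p.Val5423Phe	NP	VUS	V4797F
KMT2D	E5425K	12:49,022,655	c.16273 G > A	p.Glu5425Lys	NP	Pathogenic	E4799K
KMT2D	R5432Q	12:49,022,633	c.16295 G > A	p.Arg5432Gln	NP|Kabuki syndrome 1	CIP	R4806Q
KMT2D	R5432W	12:49,022,634	c.16294 C > T	p.Arg5432Trp	NP	Pathogenic	R4806W
KMT2D	N5437S	12:49,022,618	c.16310A > G	p.Asn5437Ser	NP	VUS	N4811S
KMT2D	T5464M	12:49,022,301	c.16391 C > T	p.Thr5464Met	NP	VUS	T4838M
KMT2D	R5471K	12:49,022,280	c.16412 G > A	p.Arg5471Lys	NP	Likely pathogenic	R4845K
KMT2D	R5471S	12:49,022,151	c.16413 G > T	p.Arg5471Ser	Kabuki syndrome 1	Likely pathogenic	R4845S
KMT2D	R5471W	12:49,022,281	c.16411A > T	p.Arg5471Trp	Kabuki syndrome 1	Likely pathogenic	R4845W
KMT2D	C5481Y	12:49,022,122	c.16442 G > A	p.Cys5481Tyr	Kabuki syndrome|NP	P/LP	C4855Y
KMT2D	F5488L	12:49,022,100	c.16464 T > A	p.Phe5488Leu	NP	VUS	F4862L
KMT2D	D5489E	12:4,9,022,097	c.16467 C > G	p.Asp5489Glu	Kabuki syndrome	VUS	D4863E
KMT2D	I5496S	12:4,9,022,077	c.16487 T > G	p.Ile5496Ser	NP	VUS	I4870S
KMT2D	R5500W	12:4,9,022,066	c.16498 C > T	p.Arg5500Trp	NP	VUS	R4874W
KMT2D	E5507D	12:4,9,022,043	c.16521 G > C	p.Glu5507Asp	NP	VUS	E4881D
KMT2D	Y5510C	12:4,9,021,865	c.16529A > G	p.Tyr5510Cys	Neurodevelopmental disorder	VUS	Y4884C
KMT2D	D5518G	12:4,9,021,841	c.16553A > G	p.Asp5518Gly	Kabuki syndrome	VUS	D4892G
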