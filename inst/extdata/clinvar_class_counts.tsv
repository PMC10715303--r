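# Germline missense class counts per gene. VUS / Conflicting / NotProvided
# counts are the published ClinVar-mining figures; the split of the
# remaining confidently-classified variants across Benign / LikelyBenign /
# LikelyPathogenic / Pathogenic is NOT published and is allocated here
# synthetically by largest-remainder over an equal split (audit column
# `published` marks which rows are real counts).
gene	clinical_class	count	published
KMT2C	VUS	289	yes
KMT2C	Conflicting	4	yes
KMT2C	NotProvided	34	yes
KMT2C	Benign	29	no
KMT2C	LikelyBenign	28	no
KMT2C	LikelyPathogenic	28	no
KMT2C	Pathogenic	28	no
KMT2D	VUS	886	yes
KMT2D	Conflicting	108	yes
KMT2D	NotProvided	21	yes
KMT2D	Benign	81	no
KMT2D	LikelyBenign	81	no
KMT2D	LikelyPathogenic	81	no
KMT2D	Pathogenic	80	no
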