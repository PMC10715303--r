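gene	count
KMT2A	598
KMT2B	275
KMT2C	440
KMT2D	1338
SETD1A	57
SETD1B	78
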