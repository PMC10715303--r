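tool	cutoff	direction	category
SIFT	0.05	lower_is_damaging	sequence_functional
SIFT4G	0.05	lower_is_damaging	sequence_functional
PolyPhen2	0.5	higher_is_damaging	sequence_functional
FATHMM	-1.5	lower_is_damaging	sequence_functional
MutationAssessor	1.935	higher_is_damaging	sequence_functional
MutationTaster	0.5	higher_is_damaging	sequence_functional
MutPred	0.5	higher_is_damaging	sequence_functional
PROVEAN	-2.5	lower_is_damaging	sequence_functional
CADD	20	higher_is_damaging	ensemble
DANN	0.5	higher_is_damaging	ensemble
fathmm_MKL	0.5	higher_is_damaging	ensemble
fathmm_XF	0.5	higher_is_damaging	ensemble
GenoCanyon	0.5	higher_is_damaging	ensemble
MetaLR	0.5	higher_is_damaging	ensemble
MetaSVM	0	higher_is_damaging	ensemble
REVEL	0.5	higher_is_damaging	ensemble
VEST4	0.5	higher_is_damaging	ensemble
GERP_RS	4.4	higher_is_damaging	evolutionary_conservation
PhyloP30way	1.6	higher_is_damaging	evolutionary_conservation
PhastCons30way	0.5	higher_is_damaging	evolutionary_conservation
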