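id	role	substrate_category	substrate_subtype	source_note
mtsD_1	MtsFused	methyl_S	mtsD	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtsF_1	MtsFused	methyl_S	mtsF	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtsH_1	MtsFused	methyl_S	mtsH	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
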