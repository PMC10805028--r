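id	role	substrate_category	substrate_subtype	source_note
mtaB_1	MtxB	methyl_O	mtaB methanol	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtaB_2	MtxB	methyl_O	mtaB methanol	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtaB_3	MtxB	methyl_O	mtaB methanol	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtaB_4	MtxB	methyl_O	mtaB methanol	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtaB_5	MtxB	methyl_O	mtaB methanol	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mttB_pyl_1	MtxB	methyl_N	mttB Pyl trimethylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mttB_pyl_2	MtxB	methyl_N	mttB Pyl trimethylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mttB_pyl_3	MtxB	methyl_N	mttB Pyl trimethylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mttB_nonpyl_1	MtxB	methyl_N	non-Pyl mttB quaternary amine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mttB_nonpyl_2	MtxB	methyl_N	non-Pyl mttB quaternary amine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtbB_1	MtxB	methyl_N	mtbB dimethylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtbB_2	MtxB	methyl_N	mtbB dimethylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtbB_3	MtxB	methyl_N	mtbB dimethylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtmB_1	MtxB	methyl_N	mtmB monomethylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtmB_2	MtxB	methyl_N	mtmB monomethylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtvB_1	MtxB	methyl_O	methoxy mtvB	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtvB_2	MtxB	methyl_O	methoxy mtvB	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtvB_3	MtxB	methyl_O	methoxy mtvB	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtsA_1	MtxB	methyl_S	mtsA	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtsA_2	MtxB	methyl_S	mtsA	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtaC_1	MtxC	methyl_O	mtaC methanol	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtaC_2	MtxC	methyl_O	mtaC methanol	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtaC_3	MtxC	methyl_O	mtaC methanol	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtaC_4	MtxC	methyl_O	mtaC methanol	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mttC_1	MtxC	methyl_N	mttC methylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mttC_2	MtxC	methyl_N	mttC methylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mttC_3	MtxC	methyl_N	mttC methylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtbC_1	MtxC	methyl_N	mtbC methylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtbC_2	MtxC	methyl_N	mtbC methylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtbC_3	MtxC	methyl_N	mtbC methylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtmC_1	MtxC	methyl_N	mtmC methylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtmC_2	MtxC	methyl_N	mtmC methylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtvC_1	MtxC	methyl_O	methoxy mtvC	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtvC_2	MtxC	methyl_O	methoxy mtvC	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtsB_1	MtxC	methyl_S	mtsB	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtsB_2	MtxC	methyl_S	mtsB	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtaA_1	MtxA	methyl_O	mtaA methanol	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtaA_2	MtxA	methyl_O	mtaA methanol	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtaA_3	MtxA	methyl_O	mtaA methanol	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtaA_4	MtxA	methyl_O	mtaA methanol	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtbA_1	MtxA	methyl_N	mtbA methylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtbA_2	MtxA	methyl_N	mtbA methylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtbA_3	MtxA	methyl_N	mtbA methylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtbA_4	MtxA	methyl_N	mtbA methylamine	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtvA_1	MtxA	methyl_O	methoxy mtvA	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
mtvA_2	MtxA	methyl_O	methoxy mtvA	synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
ramA_1	RamX	ambiguous		synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
ramA_2	RamX	ambiguous		synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
ramA_3	RamX	ambiguous		synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
ramM_1	RamX	ambiguous		synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
ramM_2	RamX	ambiguous		synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
ramS_1	RamX	ambiguous		synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
ramS_2	RamX	ambiguous		synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor
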