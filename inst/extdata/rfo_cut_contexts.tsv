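# Cut-site contexts and observed 1-bp insertions for the nine sgRNAs of a
# published common-bean hairy-root RFO-gene editing study. left3/right3 are
# the three bases on each side of the blunt cut (protospacer-strand
# orientation; the last base of left3 is the -4 position relative to the
# PAM). predicted_base is the single 1-bp insertion called at 100% by the
# reference repair model, or NA when the model split its call over several
# bases. obs_* columns give the percentage of observed 1-bp insertions
# carrying each base (NA throughout when no root carried an insertion);
# n_roots_ins is the number of roots with 1-bp insertions. strength_class /
# strength_value are the microhomology-strength calls of the reference
# model over 100-bp flanks.
target	guide	left3	right3	strength_class	strength_value	predicted_base	n_roots_ins	obs_A	obs_C	obs_G	obs_T
PvRS1	sgRNA1	TGT	GGC	average	0.5	T	0	NA	NA	NA	NA
PvRS1	sgRNA2	CTC	TCT	high	1.25	NA	2	48	48	0	4
PvRS1	sgRNA3	ATC	GTC	average	0.58	C	3	50	0	36.7	13.3
PvRS2	sgRNA1	AAA	GGG	low	0.23	A	10	75.6	18.9	1.1	4.4
PvRS2	sgRNA2	GGA	GGG	high	1.09	A	1	100	0	0	0
PvRS2	sgRNA3	CTT	GGT	average	0.41	T	3	3.9	27.8	0.9	67.4
PvSS	sgRNA1	GGT	AGT	average	0.48	NA	3	3.3	1.7	26.7	68.3
PvSS	sgRNA2	GAA	CAC	average	0.49	A	16	90.3	3.1	6.6	0
PvSS	sgRNA3	TGA	TTG	average	0.54	NA	8	25.1	29.6	15.3	28.8
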