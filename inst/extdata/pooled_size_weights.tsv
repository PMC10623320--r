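# Pooled indel-size distribution used by the synthetic cohort generator.
# Anchored to the pooled spectrum observed across 288 edited hairy roots in a
# published common-bean (P. vulgaris) RFO-gene editing study: 1-bp deletions
# 22.6% and 1-bp insertions 19.1% of all indel events, deletions three times
# as frequent as insertions overall, deletions up to 30 bp, insertions up to
# 4 bp. Only the two 1-bp frequencies, the 3:1 ratio and the size bounds were
# reported; the remaining mass is spread geometrically (ratio 0.85 over
# deletions -2..-30, ratio 0.5 over insertions +2..+4) as a modelling choice.
size	weight
-30	0.000837662149
-29	0.000985484882
-28	0.001159393978
-27	0.001363992916
-26	0.001604697548
-25	0.001887879468
-24	0.002221034668
-23	0.002612981963
-22	0.003074096427
-21	0.003616584031
-20	0.004254804743
-19	0.005005652638
-18	0.005889003104
-17	0.006928238946
-16	0.008150869348
-15	0.009589258057
-14	0.011281480067
-13	0.013272329490
-12	0.015614505282
-11	0.018370006215
-10	0.021611772017
-9	0.025425614138
-8	0.029912487221
-7	0.035191161436
-6	0.041401366396
-5	0.048707489877
-4	0.057302929267
-3	0.067415210903
-2	0.079312012827
-1	0.226000000000
1	0.191000000000
2	0.033714285714
3	0.016857142857
4	0.008428571429
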