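# Observed dominant indels (>20% occurrence within a hairy root) per sgRNA
# and Cas9 construct, as reported by a published common-bean (P. vulgaris)
# hairy-root editing study of the RFO biosynthesis genes PvRS1, PvRS2 and
# PvSS. One row per indel, ranked from high to low occurrence within each
# guide x construct pool. Guides with no dominant indel for a construct have
# no rows for it.
target	guide	construct	rank	size
PvRS1	sgRNA1	pMR394	1	-1
PvRS1	sgRNA1	pMR394	2	-4
PvRS1	sgRNA2	pMR356	1	-5
PvRS1	sgRNA2	pMR356	2	-6
PvRS1	sgRNA2	pMR356	3	-2
PvRS1	sgRNA2	pMR394	1	-10
PvRS1	sgRNA2	pMR394	2	-5
PvRS1	sgRNA2	pMR394	3	-7
PvRS1	sgRNA2	pMR394	4	-4
PvRS1	sgRNA3	pMR356	1	1
PvRS2	sgRNA1	pMR356	1	1
PvRS2	sgRNA1	pMR356	2	-8
PvRS2	sgRNA1	pMR356	3	-13
PvRS2	sgRNA1	pMR356	4	-6
PvRS2	sgRNA1	pMR394	1	2
PvRS2	sgRNA2	pMR356	1	-1
PvRS2	sgRNA2	pMR356	2	-2
PvRS2	sgRNA2	pMR394	1	-1
PvRS2	sgRNA2	pMR394	2	-2
PvRS2	sgRNA2	pMR394	3	-5
PvRS2	sgRNA3	pMR356	1	-1
PvRS2	sgRNA3	pMR356	2	-5
PvRS2	sgRNA3	pMR356	3	-7
PvRS2	sgRNA3	pMR356	4	-8
PvRS2	sgRNA3	pMR356	5	-6
PvRS2	sgRNA3	pMR356	6	-2
PvRS2	sgRNA3	pMR356	7	1
PvRS2	sgRNA3	pMR394	1	1
PvSS	sgRNA1	pMR356	1	-3
PvSS	sgRNA1	pMR356	2	-14
PvSS	sgRNA1	pMR356	3	-4
PvSS	sgRNA1	pMR356	4	-2
PvSS	sgRNA1	pMR394	1	-2
PvSS	sgRNA1	pMR394	2	-4
PvSS	sgRNA1	pMR394	3	1
PvSS	sgRNA2	pMR356	1	1
PvSS	sgRNA2	pMR356	2	-1
PvSS	sgRNA2	pMR356	3	-18
PvSS	sgRNA2	pMR394	1	1
PvSS	sgRNA2	pMR394	2	2
PvSS	sgRNA3	pMR356	1	1
PvSS	sgRNA3	pMR356	2	2
PvSS	sgRNA3	pMR356	3	-3
PvSS	sgRNA3	pMR356	4	-7
PvSS	sgRNA3	pMR356	5	-4
PvSS	sgRNA3	pMR356	6	-1
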