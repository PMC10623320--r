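# Top-5 indels predicted by three repair models (Lindel, the Bae
# microhomology model, inDelphi) for the nine sgRNAs of a published
# common-bean hairy-root RFO-gene editing study. One row per predicted entry
# in printed order; a size can recur within a model when the predicted
# outcomes differ (e.g. 1-bp insertions of different bases).
target	guide	model	rank	size
PvRS1	sgRNA1	Lindel	1	1
PvRS1	sgRNA1	Lindel	2	-1
PvRS1	sgRNA1	Lindel	3	-8
PvRS1	sgRNA1	Lindel	4	3
PvRS1	sgRNA1	Lindel	5	1
PvRS1	sgRNA1	Bae	1	-8
PvRS1	sgRNA1	Bae	2	-10
PvRS1	sgRNA1	Bae	3	-11
PvRS1	sgRNA1	Bae	4	-7
PvRS1	sgRNA1	Bae	5	-18
PvRS1	sgRNA1	inDelphi	1	-3
PvRS1	sgRNA1	inDelphi	2	-1
PvRS1	sgRNA1	inDelphi	3	1
PvRS1	sgRNA1	inDelphi	4	-14
PvRS1	sgRNA1	inDelphi	5	-9
PvRS1	sgRNA2	Lindel	1	1
PvRS1	sgRNA2	Lindel	2	-12
PvRS1	sgRNA2	Lindel	3	-4
PvRS1	sgRNA2	Lindel	4	-2
PvRS1	sgRNA2	Lindel	5	-2
PvRS1	sgRNA2	Bae	1	-12
PvRS1	sgRNA2	Bae	2	-15
PvRS1	sgRNA2	Bae	3	-29
PvRS1	sgRNA2	Bae	4	-32
PvRS1	sgRNA2	Bae	5	-20
PvRS1	sgRNA2	inDelphi	1	-12
PvRS1	sgRNA2	inDelphi	2	-2
PvRS1	sgRNA2	inDelphi	3	-4
PvRS1	sgRNA2	inDelphi	4	1
PvRS1	sgRNA2	inDelphi	5	-9
PvRS1	sgRNA3	Lindel	1	1
PvRS1	sgRNA3	Lindel	2	-3
PvRS1	sgRNA3	Lindel	3	-3
PvRS1	sgRNA3	Lindel	4	-7
PvRS1	sgRNA3	Lindel	5	3
PvRS1	sgRNA3	Bae	1	-21
PvRS1	sgRNA3	Bae	2	-23
PvRS1	sgRNA3	Bae	3	-17
PvRS1	sgRNA3	Bae	4	-22
PvRS1	sgRNA3	Bae	5	-27
PvRS1	sgRNA3	inDelphi	1	-3
PvRS1	sgRNA3	inDelphi	2	-7
PvRS1	sgRNA3	inDelphi	3	1
PvRS1	sgRNA3	inDelphi	4	-10
PvRS1	sgRNA3	inDelphi	5	-3
PvRS2	sgRNA1	Lindel	1	1
PvRS2	sgRNA1	Lindel	2	-21
PvRS2	sgRNA1	Lindel	3	-2
PvRS2	sgRNA1	Lindel	4	-5
PvRS2	sgRNA1	Lindel	5	3
PvRS2	sgRNA1	Bae	1	-3
PvRS2	sgRNA1	Bae	2	-4
PvRS2	sgRNA1	Bae	3	-17
PvRS2	sgRNA1	Bae	4	-21
PvRS2	sgRNA1	Bae	5	-20
PvRS2	sgRNA1	inDelphi	1	1
PvRS2	sgRNA1	inDelphi	2	-22
PvRS2	sgRNA1	inDelphi	3	-17
PvRS2	sgRNA1	inDelphi	4	-1
PvRS2	sgRNA1	inDelphi	5	-1
PvRS2	sgRNA2	Lindel	1	-5
PvRS2	sgRNA2	Lindel	2	-4
PvRS2	sgRNA2	Lindel	3	-16
PvRS2	sgRNA2	Lindel	4	-2
PvRS2	sgRNA2	Lindel	5	-3
PvRS2	sgRNA2	Bae	1	-11
PvRS2	sgRNA2	Bae	2	-12
PvRS2	sgRNA2	Bae	3	-16
PvRS2	sgRNA2	Bae	4	-11
PvRS2	sgRNA2	Bae	5	-15
PvRS2	sgRNA2	inDelphi	1	-3
PvRS2	sgRNA2	inDelphi	2	1
PvRS2	sgRNA2	inDelphi	3	-4
PvRS2	sgRNA2	inDelphi	4	-11
PvRS2	sgRNA2	inDelphi	5	-12
PvRS2	sgRNA3	Lindel	1	1
PvRS2	sgRNA3	Lindel	2	-1
PvRS2	sgRNA3	Lindel	3	-1
PvRS2	sgRNA3	Lindel	4	-8
PvRS2	sgRNA3	Lindel	5	-9
PvRS2	sgRNA3	Bae	1	-2
PvRS2	sgRNA3	Bae	2	-9
PvRS2	sgRNA3	Bae	3	-10
PvRS2	sgRNA3	Bae	4	-15
PvRS2	sgRNA3	Bae	5	-20
PvRS2	sgRNA3	inDelphi	1	1
PvRS2	sgRNA3	inDelphi	2	-6
PvRS2	sgRNA3	inDelphi	3	-9
PvRS2	sgRNA3	inDelphi	4	-10
PvRS2	sgRNA3	inDelphi	5	-8
PvSS	sgRNA1	Lindel	1	1
PvSS	sgRNA1	Lindel	2	-3
PvSS	sgRNA1	Lindel	3	-11
PvSS	sgRNA1	Lindel	4	-1
PvSS	sgRNA1	Lindel	5	-1
PvSS	sgRNA1	Bae	1	-8
PvSS	sgRNA1	Bae	2	-11
PvSS	sgRNA1	Bae	3	-17
PvSS	sgRNA1	Bae	4	-18
PvSS	sgRNA1	Bae	5	-19
PvSS	sgRNA1	inDelphi	1	-3
PvSS	sgRNA1	inDelphi	2	1
PvSS	sgRNA1	inDelphi	3	-11
PvSS	sgRNA1	inDelphi	4	-8
PvSS	sgRNA1	inDelphi	5	-10
PvSS	sgRNA2	Lindel	1	-2
PvSS	sgRNA2	Lindel	2	-5
PvSS	sgRNA2	Lindel	3	-1
PvSS	sgRNA2	Lindel	4	-10
PvSS	sgRNA2	Lindel	5	-18
PvSS	sgRNA2	Bae	1	-11
PvSS	sgRNA2	Bae	2	-18
PvSS	sgRNA2	Bae	3	-10
PvSS	sgRNA2	Bae	4	-5
PvSS	sgRNA2	Bae	5	-19
PvSS	sgRNA2	inDelphi	1	-5
PvSS	sgRNA2	inDelphi	2	-11
PvSS	sgRNA2	inDelphi	3	1
PvSS	sgRNA2	inDelphi	4	-10
PvSS	sgRNA2	inDelphi	5	-2
PvSS	sgRNA3	Lindel	1	-4
PvSS	sgRNA3	Lindel	2	1
PvSS	sgRNA3	Lindel	3	3
PvSS	sgRNA3	Lindel	4	-1
PvSS	sgRNA3	Lindel	5	-1
PvSS	sgRNA3	Bae	1	-19
PvSS	sgRNA3	Bae	2	-27
PvSS	sgRNA3	Bae	3	-30
PvSS	sgRNA3	Bae	4	-30
PvSS	sgRNA3	Bae	5	-24
PvSS	sgRNA3	inDelphi	1	-4
PvSS	sgRNA3	inDelphi	2	1
PvSS	sgRNA3	inDelphi	3	-3
PvSS	sgRNA3	inDelphi	4	1
PvSS	sgRNA3	inDelphi	5	-1
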