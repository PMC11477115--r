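# SYNTHETIC stand-in codon-frequency table for s_cerevisiae
# Not a snapshot of any public codon-usage database: frequencies are
# generated from a parametric model (typical amino-acid composition,
# host-typical GC3 and a preferred-codon boost) and are intended for
# demonstrations and tests of the host-comparison machinery only.
# columns: codon, aa, freq_per_thousand (sums to 1000)
codon	aa	freq_per_thousand
TTT	F	5.2
TTC	F	7.8391
TTA	L	5.2483
TTG	L	7.9118
TCT	S	8.8784
TCC	S	2.2124
TCA	S	3.6097
TCG	S	2.2124
TAT	Y	4.2667
TAC	Y	6.4321
TAA	Stop	366.6667
TAG	Stop	100
TGT	C	5.0852
TGC	C	1.2672
TGA	Stop	200
TGG	W	4.3464
CTT	L	5.2483
CTC	L	3.2167
CTA	L	5.2483
CTG	L	3.2167
CCT	P	3.7106
CCC	P	2.2742
CCA	P	9.1265
CCG	P	2.2742
CAT	H	2.9334
CAC	H	4.422
CAA	Q	11.241
CAG	Q	2.8011
CGT	R	2.7073
CGC	R	1.6593
CGA	R	2.7073
CGG	R	1.6593
ATT	I	9.302
ATC	I	4.6359
ATA	I	3.7819
ATG	M	8.0241
ACT	T	10.3551
ACC	T	2.5804
ACA	T	4.2101
ACG	T	2.5804
AAT	N	5.7334
AAC	N	8.6431
AAA	K	15.7909
AAG	K	3.9349
AGT	S	3.6097
AGC	S	2.2124
AGA	R	6.6588
AGG	R	1.6593
GTT	V	11.5836
GTC	V	2.8865
GTA	V	4.7096
GTG	V	2.8865
GCT	A	13.6898
GCC	A	3.4113
GCA	A	5.5658
GCG	A	3.4113
GAT	D	6.9334
GAC	D	10.4521
GAA	E	16.8615
GAG	E	4.2017
GGT	G	12.6367
GGC	G	3.1489
GGA	G	5.1377
GGG	G	3.1489
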