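# SYNTHETIC stand-in codon-frequency table for a_thaliana
# Not a snapshot of any public codon-usage database: frequencies are
# generated from a parametric model (typical amino-acid composition,
# host-typical GC3 and a preferred-codon boost) and are intended for
# demonstrations and tests of the host-comparison machinery only.
# columns: codon, aa, freq_per_thousand (sums to 1000)
codon	aa	freq_per_thousand
TTT	F	8.8307
TTC	F	4.2084
TTA	L	5.0101
TTG	L	3.9365
TCT	S	6.2411
TCC	S	2.9743
TCA	S	3.7854
TCG	S	2.9743
TAT	Y	7.2457
TAC	Y	3.453
TAA	Stop	366.6667
TAG	Stop	100
TGT	C	4.3022
TGC	C	2.0502
TGA	Stop	200
TGG	W	4.3464
CTT	L	8.2603
CTC	L	3.9365
CTA	L	5.0101
CTG	L	3.9365
CCT	P	6.7921
CCC	P	3.2369
CCA	P	4.1196
CCG	P	3.2369
CAT	H	4.9814
CAC	H	2.374
CAA	Q	9.51
CAG	Q	4.5321
CGT	R	2.8391
CGC	R	2.2307
CGA	R	2.8391
CGG	R	2.2307
ATT	I	6.9228
ATC	I	6.5982
ATA	I	4.1989
ATG	M	8.0241
ACT	T	7.7065
ACC	T	3.6726
ACA	T	4.6742
ACG	T	3.6726
AAT	N	9.7365
AAC	N	4.64
AAA	K	8.5936
AAG	K	11.1323
AGT	S	3.7854
AGC	S	2.9743
AGA	R	4.6809
AGG	R	2.2307
GTT	V	8.6208
GTC	V	4.1083
GTA	V	5.2288
GTG	V	4.1083
GCT	A	10.1882
GCC	A	4.8553
GCA	A	6.1795
GCG	A	4.8553
GAT	D	11.7743
GAC	D	5.6112
GAA	E	9.1762
GAG	E	11.887
GGT	G	5.7041
GGC	G	4.4818
GGA	G	9.4045
GGG	G	4.4818
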