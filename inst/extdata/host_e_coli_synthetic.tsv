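# SYNTHETIC stand-in codon-frequency table for e_coli
# Not a snapshot of any public codon-usage database: frequencies are
# generated from a parametric model (typical amino-acid composition,
# host-typical GC3 and a preferred-codon boost) and are intended for
# demonstrations and tests of the host-comparison machinery only.
# columns: codon, aa, freq_per_thousand (sums to 1000)
codon	aa	freq_per_thousand
TTT	F	2.578
TTC	F	10.4612
TTA	L	3.1666
TTG	L	3.8703
TCT	S	8.3993
TCC	S	3.092
TCA	S	2.5298
TCG	S	3.092
TAT	Y	2.1152
TAC	Y	8.5835
TAA	Stop	366.6667
TAG	Stop	100
TGT	C	1.2559
TGC	C	5.0965
TGA	Stop	200
TGG	W	4.3464
CTT	L	3.1666
CTC	L	3.8703
CTA	L	3.1666
CTG	L	12.8498
CCT	P	2.3881
CCC	P	2.9188
CCA	P	2.3881
CCG	P	9.6906
CAT	H	1.4542
CAC	H	5.9012
CAA	Q	2.7763
CAG	Q	11.2659
CGT	R	1.7944
CGC	R	7.2816
CGA	R	1.7944
CGG	R	2.1932
ATT	I	1.7517
ATC	I	14.2164
ATA	I	1.7517
ATG	M	8.0241
ACT	T	2.7095
ACC	T	10.9951
ACA	T	2.7095
ACG	T	3.3117
AAT	N	2.8424
AAC	N	11.5341
AAA	K	14.4181
AAG	K	5.3077
AGT	S	2.5298
AGC	S	3.092
AGA	R	1.7944
AGG	R	2.1932
GTT	V	3.031
GTC	V	3.7046
GTA	V	3.031
GTG	V	12.2996
GCT	A	3.5821
GCC	A	4.3781
GCA	A	3.5821
GCG	A	14.5359
GAT	D	3.4373
GAC	D	13.9482
GAA	E	15.3956
GAG	E	5.6675
GGT	G	3.3066
GGC	G	13.4178
GGA	G	3.3066
GGG	G	4.0413
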