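# SYNTHETIC stand-in codon-frequency table for n_tabacum
# Not a snapshot of any public codon-usage database: frequencies are
# generated from a parametric model (typical amino-acid composition,
# host-typical GC3 and a preferred-codon boost) and are intended for
# demonstrations and tests of the host-comparison machinery only.
# columns: codon, aa, freq_per_thousand (sums to 1000)
codon	aa	freq_per_thousand
TTT	F	9.0599
TTC	F	3.9792
TTA	L	5.1691
TTG	L	3.7432
TCT	S	6.4392
TCC	S	2.8282
TCA	S	3.9056
TCG	S	2.8282
TAT	Y	7.4338
TAC	Y	3.265
TAA	Stop	366.6667
TAG	Stop	100
TGT	C	4.4138
TGC	C	1.9386
TGA	Stop	200
TGG	W	4.3464
CTT	L	8.5225
CTC	L	3.7432
CTA	L	5.1691
CTG	L	3.7432
CCT	P	6.9963
CCC	P	3.0729
CCA	P	4.2435
CCG	P	3.0729
CAT	H	5.1107
CAC	H	2.2447
CAA	Q	9.7568
CAG	Q	4.2853
CGT	R	2.9292
CGC	R	2.1211
CGA	R	2.9292
CGG	R	2.1211
ATT	I	7.1308
ATC	I	6.2639
ATA	I	4.3251
ATG	M	8.0241
ACT	T	7.9381
ACC	T	3.4865
ACA	T	4.8147
ACG	T	3.4865
AAT	N	9.9891
AAC	N	4.3873
AAA	K	13.706
AAG	K	6.0198
AGT	S	3.9056
AGC	S	2.8282
AGA	R	4.8294
AGG	R	2.1211
GTT	V	8.8799
GTC	V	3.9002
GTA	V	5.3859
GTG	V	3.9002
GCT	A	10.4945
GCC	A	4.6093
GCA	A	6.3652
GCG	A	4.6093
GAT	D	12.0799
GAC	D	5.3056
GAA	E	14.6352
GAG	E	6.428
GGT	G	5.8756
GGC	G	4.2547
GGA	G	9.6872
GGG	G	4.2547
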