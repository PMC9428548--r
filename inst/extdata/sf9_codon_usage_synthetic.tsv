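# Synthetic stand-in for a Spodoptera frugiperda (Sf9) codon-usage table.
# Fractions are representative of lepidopteran codon preferences, not a
# transcription of any published Sf9 table; per-amino-acid fractions sum to 1.
# columns: codon <TAB> amino_acid (one-letter, * = stop) <TAB> fraction
codon	amino_acid	fraction
GCT	A	0.31
GCC	A	0.26
GCA	A	0.27
GCG	A	0.16
CGT	R	0.17
CGC	R	0.16
CGA	R	0.13
CGG	R	0.09
AGA	R	0.25
AGG	R	0.20
AAT	N	0.52
AAC	N	0.48
GAT	D	0.55
GAC	D	0.45
TGT	C	0.48
TGC	C	0.52
CAA	Q	0.44
CAG	Q	0.56
GAA	E	0.46
GAG	E	0.54
GGT	G	0.30
GGC	G	0.24
GGA	G	0.30
GGG	G	0.16
CAT	H	0.52
CAC	H	0.48
ATT	I	0.41
ATC	I	0.38
ATA	I	0.21
TTA	L	0.10
TTG	L	0.19
CTT	L	0.15
CTC	L	0.17
CTA	L	0.10
CTG	L	0.29
AAA	K	0.42
AAG	K	0.58
ATG	M	1.00
TTT	F	0.48
TTC	F	0.52
CCT	P	0.30
CCC	P	0.23
CCA	P	0.32
CCG	P	0.15
TCT	S	0.19
TCC	S	0.16
TCA	S	0.18
TCG	S	0.12
AGT	S	0.17
AGC	S	0.18
ACT	T	0.30
ACC	T	0.26
ACA	T	0.28
ACG	T	0.16
TGG	W	1.00
TAT	Y	0.49
TAC	Y	0.51
GTT	V	0.28
GTC	V	0.24
GTA	V	0.17
GTG	V	0.31
TAA	*	0.41
TAG	*	0.23
TGA	*	0.36
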