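# Reference codon usage stratum summary from a published genome-wide survey
# of species across the three domains of life: mean and standard deviation of
# codon usage (percent of all codons, stop codons included) in species with
# GC content < 45% versus >= 45%, and the printed fold change (ratio of the
# two means, rounded to two decimals). Average GC of the strata: 36.6 / 59.1.
codon	aa	mean_lt45	sd_lt45	mean_ge45	sd_ge45	fc_printed
AAA	K	5.54	1.93	1.60	1.29	0.29
AAT	N	3.70	1.44	1.08	0.68	0.29
AAG	K	1.94	0.81	2.06	0.73	1.06
AAC	N	1.57	0.50	1.94	0.33	1.23
ATA	I	2.04	1.61	0.42	0.58	0.21
ATT	I	4.19	1.23	1.51	1.11	0.36
ATG	M	2.33	0.32	2.33	0.39	1.00
ATC	I	1.68	0.67	3.21	0.74	1.91
TTA	L	3.62	1.60	0.55	0.67	0.15
TTT	F	3.45	0.94	1.27	0.90	0.37
TTG	L	1.66	0.64	1.27	0.73	0.76
TTC	F	1.20	0.48	2.32	0.64	1.94
TAA	*	0.21	0.07	0.10	0.07	0.51
TAT	Y	2.61	0.70	1.10	0.60	0.42
TAG	*	0.06	0.03	0.06	0.03	0.90
TAC	Y	1.05	0.38	1.49	0.43	1.42
ACA	T	1.87	0.53	0.55	0.40	0.30
ACT	T	1.68	0.45	0.53	0.37	0.31
ACG	T	0.75	0.42	1.70	0.61	2.27
ACC	T	1.00	0.56	2.67	0.74	2.66
AGA	R	1.25	0.65	0.26	0.30	0.21
AGT	S	1.43	0.34	0.50	0.33	0.35
AGG	R	0.44	0.44	0.37	0.51	0.83
AGC	S	0.97	0.52	1.63	0.38	1.68
TCA	S	1.47	0.46	0.47	0.33	0.32
TCT	S	1.62	0.56	0.48	0.37	0.30
TCG	S	0.47	0.24	1.41	0.56	2.98
TCC	S	0.62	0.46	1.23	0.44	1.99
TGA	*	0.12	0.22	0.17	0.08	1.44
TGT	C	0.64	0.25	0.27	0.18	0.43
TGG	W	0.93	0.28	1.40	0.17	1.51
TGC	C	0.36	0.28	0.68	0.19	1.88
CAA	Q	2.57	0.87	0.99	0.70	0.39
CAT	H	1.32	0.31	0.90	0.40	0.69
CAG	Q	1.19	0.83	2.71	0.60	2.28
CAC	H	0.63	0.33	1.28	0.39	2.03
CTA	L	1.01	0.38	0.34	0.33	0.34
CTT	L	1.86	0.62	0.98	0.62	0.53
CTG	L	1.01	1.03	4.95	1.71	4.91
CTC	L	0.72	0.52	2.29	1.28	3.19
GAA	E	4.80	0.97	2.70	1.12	0.56
GAT	D	3.88	0.70	2.25	0.95	0.58
GAG	E	1.84	0.91	3.12	1.18	1.69
GAC	D	1.36	0.61	3.31	1.26	2.44
CCA	P	1.29	0.39	0.53	0.35	0.41
CCT	P	1.29	0.35	0.57	0.32	0.44
CCG	P	0.54	0.38	2.46	0.78	4.55
CCC	P	0.47	0.46	1.40	0.66	2.94
CGA	R	0.44	0.24	0.41	0.23	0.94
CGT	R	1.02	0.60	1.10	0.53	1.08
CGG	R	0.29	0.30	1.39	0.81	4.86
CGC	R	0.57	0.40	3.01	1.15	5.26
GCA	A	2.29	0.57	1.36	0.64	0.60
GCT	A	2.39	0.58	1.17	0.63	0.49
GCG	A	0.95	0.60	3.95	1.61	4.15
GCC	A	1.16	0.70	4.65	1.75	4.00
GGA	G	1.97	0.75	0.88	0.49	0.45
GGT	G	2.19	0.67	1.46	0.61	0.67
GGG	G	0.87	0.41	1.39	0.52	1.61
GGC	G	1.22	0.63	4.34	1.35	3.56
GTA	V	1.80	0.64	0.67	0.47	0.37
GTT	V	2.42	0.64	1.07	0.69	0.44
GTG	V	1.30	0.69	3.11	0.85	2.39
GTC	V	0.86	0.48	2.67	1.15	3.11
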