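# Human proteome homo-repeat / disease contingency counts.
# N_b: proteins with a homo-repeat of the given amino acid, length >= 5,
#      among N = 59053 human proteins (reviewed + unreviewed Uniprot entries).
# N_ab: of those, proteins with an OMIM disease annotation
#       (N_a = 2501 disease-annotated proteins in total).
amino_acid	N_b	N_ab
C	38	2
M	3	0
F	56	1
I	25	1
L	1503	125
V	49	7
W	1	0
Y	7	0
A	1300	105
G	836	67
T	190	16
S	1175	86
Q	529	41
N	24	1
E	1625	108
D	262	23
H	148	16
R	270	18
K	554	27
P	1363	114
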