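anticodon	gene_copy_number
AGC	11
UGC	5
ACG	6
UCU	11
CCU	1
CCG	1
UCG	1
GUU	10
GUC	16
GCA	4
UUG	9
CUG	1
UUC	14
CUC	2
GCC	16
UCC	3
CCC	2
GUG	7
AAU	13
UAU	2
UAA	7
CAA	10
UAG	3
GAG	1
UUU	7
CUU	14
CAU	10
GAA	10
AGG	10
UGG	2
AGA	11
UGA	3
CGA	1
GCU	4
AGU	11
UGU	1
CGU	1
CCA	6
GUA	8
AAC	14
UAC	2
CAC	2
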