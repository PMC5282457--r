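# synthetic example unique-sequence count table (three rounds)
# generated by the selexr simulator conventions; not real data
sequence	R1	R2	R3
TCTCAGGAGCGATATTATGTCACTTAATACGTGACTGATC	500	2000	8000
CTCTGAAGATAGCGCCGCACTGTCCGGCGTACAGTCAGCT	140	280	560
TCTCAGGAGCGATTTTATGTCACTTAATACGTGACTGATC	30	120	480
TCTCAGGAGCGATATTATGTCGCCTAATACGTGACTGATC	12	48	192
CTCTGAAGATAGCGCCGCACTGTCCGGCGTCCAGTCAGCT	9	18	36
ACCTGCGAGATTGGTTACTCGTTTGTGTTTCCTATCGTCC	3	1	0
CCAGATCGTAATTCTCATTCAGAACGGGATTTACTCGGAC	3	1	0
CCTAAGTGGGTGGGGGATCTACCCAGGCACATACCTGTGA	3	1	0
GGTAATTCAGATACGTACGACTAACGGCGACCGAGTCACT	3	1	0
TCATCCTGAAAAGCCAGCATGCGCTCTGGAGTTAATATAC	3	1	0
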