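gene	region	cds_start	sequence
BRAF	codons_594_604	1780	GATTTTGGTCTAGCTACAGTGAAATCTCGATGG
NRAS	codons_8_17	22	GTGGTTGGAGCAGGTGGTGTTGGGAAAAGC
NRAS	codons_57_65	169	GATACAGCAGGACAAGAAGAGTATTCA
KIT	codons_555_578	1663	GTGCAGTGGAAGGTTGTTGAAGAAATTAATGGAAATAATTATGTTTATATTGATCCAACACAACTTCCATAT
KIT	codons_640_644	1918	CATGAAAAGACTGGG
KIT	codons_814_818	2440	ATTAATGACATTAAA
GNAQ	codons_207_211	619	GGAGGTCAACGTTCA
GNA11	codons_207_211	619	GGAGGTCAGCGTTCA
MAP2K1	codons_119_126	355	GAAATTTGTAAATTTCCAGGTGAT
MAP2K2	codons_55_62	163	GCTAATTTCGGTGAACAGAAACTT
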