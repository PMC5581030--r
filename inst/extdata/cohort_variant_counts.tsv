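gene	protein_change	cdna_change	n_biochip
BRAF	V600E	c.1799T>A	111
BRAF	V600E	c.1799_1800delTGinsAA	0
BRAF	V600K	c.1798_1799delGTinsAA	14
BRAF	V600R	c.1798_1799delGTinsAG	3
BRAF	V600M	c.1798G>A	1
BRAF	V600G	c.1799T>G	0
BRAF	V600D	c.1799_1800delTGinsAT	0
NRAS	G12C	c.34G>T	0
NRAS	G12S	c.34G>A	0
NRAS	G12D	c.35G>A	0
NRAS	G13R	c.37G>C	1
NRAS	G13D	c.38G>A	1
NRAS	G13V	c.38G>T	0
NRAS	Q61P	c.182A>C	0
NRAS	Q61R	c.182A>G	17
NRAS	Q61H	c.183A>C	2
NRAS	Q61H	c.183A>T	1
NRAS	Q61K	c.181C>A	20
NRAS	Q61L	c.182A>T	3
KIT	W557R	c.1669T>A	0
KIT	W557R	c.1669T>C	0
KIT	V559A	c.1676T>C	0
KIT	V559D	c.1676T>A	0
KIT	L576P	c.1727T>C	5
KIT	K642E	c.1924A>G	1
KIT	D816H	c.2446G>C	0
KIT	D816Y	c.2446G>T	0
KIT	D816V	c.2447A>T	0
GNAQ	Q209P	c.626A>C	2
GNAQ	Q209L	c.626A>T	2
GNAQ	Q209R	c.626A>G	0
GNA11	Q209L	c.626A>T	2
GNA11	Q209P	c.626A>C	0
MAP2K1	C121S	c.361T>A	0
MAP2K1	C121S	c.362G>C	0
MAP2K1	P124S	c.370C>T	2
MAP2K1	P124L	c.371C>T	0
MAP2K2	F57C	c.170T>G	0
MAP2K2	Q60P	c.179A>C	0
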