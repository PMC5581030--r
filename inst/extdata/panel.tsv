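gene	protein_change	cdna_change	group_id
BRAF	V600E	c.1799T>A	BRAF_600
BRAF	V600E	c.1799_1800delTGinsAA	BRAF_600
BRAF	V600K	c.1798_1799delGTinsAA	BRAF_600
BRAF	V600R	c.1798_1799delGTinsAG	BRAF_600
BRAF	V600M	c.1798G>A	BRAF_600
BRAF	V600G	c.1799T>G	BRAF_600
BRAF	V600D	c.1799_1800delTGinsAT	BRAF_600
NRAS	G12C	c.34G>T	NRAS_12_13
NRAS	G12S	c.34G>A	NRAS_12_13
NRAS	G12D	c.35G>A	NRAS_12_13
NRAS	G13R	c.37G>C	NRAS_12_13
NRAS	G13D	c.38G>A	NRAS_12_13
NRAS	G13V	c.38G>T	NRAS_12_13
NRAS	Q61P	c.182A>C	NRAS_61
NRAS	Q61R	c.182A>G	NRAS_61
NRAS	Q61H	c.183A>C	NRAS_61
NRAS	Q61H	c.183A>T	NRAS_61
NRAS	Q61K	c.181C>A	NRAS_61
NRAS	Q61L	c.182A>T	NRAS_61
KIT	W557R	c.1669T>A	KIT_557_559
KIT	W557R	c.1669T>C	KIT_557_559
KIT	V559A	c.1676T>C	KIT_557_559
KIT	V559D	c.1676T>A	KIT_557_559
KIT	L576P	c.1727T>C	KIT_576
KIT	K642E	c.1924A>G	KIT_642
KIT	D816H	c.2446G>C	KIT_816
KIT	D816Y	c.2446G>T	KIT_816
KIT	D816V	c.2447A>T	KIT_816
GNAQ	Q209P	c.626A>C	GNAQ_209
GNAQ	Q209L	c.626A>T	GNAQ_209
GNAQ	Q209R	c.626A>G	GNAQ_209
GNA11	Q209L	c.626A>T	GNA11_209
GNA11	Q209P	c.626A>C	GNA11_209
MAP2K1	C121S	c.361T>A	MAP2K1_121_124
MAP2K1	C121S	c.362G>C	MAP2K1_121_124
MAP2K1	P124S	c.370C>T	MAP2K1_121_124
MAP2K1	P124L	c.371C>T	MAP2K1_121_124
MAP2K2	F57C	c.170T>G	MAP2K2_57_60
MAP2K2	Q60P	c.179A>C	MAP2K2_57_60
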