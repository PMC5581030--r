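sample_id,is_cell_line,biochip,ngs,sanger,clamp_sanger
2,FALSE,BRAF:V600E:c.1799T>A,BRAF:V600E:c.1799T>A,,
31,FALSE,WT,WT,,
52,FALSE,BRAF:V600E:c.1799T>A,BRAF:V600E:c.1799T>A,,
91,FALSE,WT,WT,,
92,FALSE,BRAF:V600E:c.1799T>A,BRAF:V600E:c.1799T>A,,
93,FALSE,NRAS:Q61K:c.181C>A,WT,WT,NRAS:Q61K:c.181C>A
94,FALSE,BRAF:V600E:c.1799T>A;MAP2K1:P124S:c.370C>T,BRAF:V600E:c.1799T>A;MAP2K1:P124S:c.370C>T,,
95,FALSE,BRAF:V600E:c.1799T>A,BRAF:V600E:c.1799T>A,,
96,FALSE,BRAF:V600E:c.1799T>A,WT,,
97,FALSE,BRAF:V600E:c.1799T>A,BRAF:V600E:c.1799T>A,,
98,FALSE,WT,WT,,
99,FALSE,BRAF:V600K:c.1798_1799delGTinsAA,BRAF:V600K:c.1798_1799delGTinsAA,,
100,FALSE,BRAF:V600E:c.1799T>A,BRAF:V600E:c.1799T>A,,
101,FALSE,WT,KIT:M541L:c.1621A>C,,
102,FALSE,BRAF:V600E:c.1799T>A,BRAF:V600E:c.1799T>A,,
103,FALSE,NRAS:Q61H:c.182A>C,NRAS:Q61H:c.182A>C,,
104,FALSE,WT,WT,,
105,FALSE,BRAF:V600E:c.1799T>A,BRAF:V600E:c.1799T>A,,
106,FALSE,BRAF:V600K:c.1798_1799delGTinsAA,KIT:V50L:c.148G>T,WT,BRAF:V600K:c.1798_1799delGTinsAA
107,FALSE,BRAF:V600E:c.1799T>A,BRAF:V600E:c.1799T>A,,
108,FALSE,NRAS:G13R:c.37G>C,NRAS:G13R:c.37G>C,,
109,FALSE,NRAS:Q61K:c.181C>A,NRAS:Q61K:c.181C>A,,
110,FALSE,BRAF:V600E:c.1799T>A,BRAF:V600E:c.1799T>A,,
111,FALSE,BRAF:V600E:c.1799T>A,KIT:M541L:c.1621A>C;BRAF:V600E:c.1799T>A,,
112,FALSE,NRAS:Q61K:c.181C>A,WT,WT,NRAS:Q61K:c.181C>A
SK-MEL2,TRUE,NRAS:Q61R:c.182A>G,NRAS:Q61R:c.182A>G;KIT:M541L:c.1621A>C;KIT:G245S:c.733G>A,,
Mel Il,TRUE,BRAF:V600K:c.1798_1799delGTinsAA,BRAF:V600K:c.1798_1799delGTinsAA;BRAF:R389C:c.1165C>T,,
Mel Ibr,TRUE,BRAF:V600E:c.1799T>A,BRAF:V600E:c.1799T>A,,
Mel Rac,TRUE,NRAS:Q61R:c.182A>G,NRAS:Q61R:c.182A>G,,
Mel Cher,TRUE,NRAS:Q61R:c.182A>G,WT,WT,NRAS:Q61R:c.182A>G
Mel Z,TRUE,BRAF:V600E:c.1799T>A,BRAF:V600E:c.1799T>A,,
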