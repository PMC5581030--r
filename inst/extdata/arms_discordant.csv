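sample_id,is_cell_line,biochip,arms,sanger,clamp_sanger
163,FALSE,BRAF:V600E:c.1799T>A,WT,BRAF:V600E:c.1799T>A,BRAF:V600E:c.1799T>A
191,FALSE,BRAF:V600K:c.1798_1799delGTinsAA,WT,BRAF:V600K:c.1798_1799delGTinsAA,BRAF:V600K:c.1798_1799delGTinsAA
219,FALSE,WT,BRAF:V600R:c.1798_1799delGTinsAG,WT,BRAF:V600V:c.1800G>A
223,FALSE,WT,BRAF:V600E:c.1799T>A,WT,WT
226,FALSE,WT,BRAF:V600K:c.1798_1799delGTinsAA,WT,WT
235,FALSE,BRAF:V600M:c.1798G>A,WT,WT,BRAF:V600M:c.1798G>A
238,FALSE,WT,BRAF:V600E:c.1799T>A,BRAF:T599_V600insT:c.1797_1798insACA,BRAF:T599_V600insT:c.1797_1798insACA
239,FALSE,BRAF:V600E:c.1799T>A,BRAF:V600K:c.1798_1799delGTinsAA,WT,BRAF:V600E:c.1799T>A
241,FALSE,WT,BRAF:V600K:c.1798_1799delGTinsAA,WT,WT
242,FALSE,WT,BRAF:V600K:c.1798_1799delGTinsAA,WT,WT
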