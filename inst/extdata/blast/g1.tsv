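# BLASTP 2.x, toy fixture: query proteome vs genome g1 (self)
pA	pA	100.0	120	0	0	1	120	1	120	1e-80	200.0
pB	pB	100.0	180	0	0	1	180	1	180	1e-120	300.0
pC	pC	100.0	90	0	0	1	90	1	90	1e-45	120.0
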