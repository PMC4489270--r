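# BLASTP 2.x, toy fixture: query proteome vs genome g4
pA	g4_hitA	35.0	112	65	6	5	116	4	114	2e-07	49.9
pB	g4_hitB	40.0	168	80	4	1	168	1	168	1e-15	60.0
pC	g4_hitC	42.0	88	48	3	1	88	1	88	1e-12	55.0
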