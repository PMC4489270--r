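# BLASTP 2.x, toy fixture: query proteome vs genome g2
pA	g2_hitA	62.0	118	40	2	1	118	1	118	1e-40	100.0
pB	g2_hitB	70.5	176	30	1	1	176	1	176	1e-60	150.0
pB	g2_decoyB	45.0	150	70	4	10	160	5	155	1e-20	90.0
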