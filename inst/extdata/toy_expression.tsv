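cell_id	p1	p2	p3	p4	p5
c1	5.1	4.2	NA	6.0	3.3
c2	5.0	4.4	2.1	NA	3.1
c3	NA	1.2	2.2	5.8	7.4
c4	4.8	1.0	2.0	5.5	7.0
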