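multiplicity	Minimal	PowerPlexY12	Yfiler	PowerPlexY23	Microreader24Y
1	590	674	813	867	877
2	74	70	40	20	15
3	16	12	2	1	1
4	9	6	1	0	0
5	3	3	0	0	0
6	5	1	0	0	0
7	0	1	1	0	0
8	0	1	0	0	0
9	2	0	0	0	0
10	1	0	0	0	0
15	1	0	0	0	0
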