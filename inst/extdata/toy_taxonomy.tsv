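1	1	no rank	root
2	1	family	Phasianidae
3	2	genus	Gallus
4	3	species	Gallus gallus
5	2	genus	Meleagris
6	5	species	Meleagris gallopavo
7	1	family	Suidae
8	7	genus	Sus
9	8	species	Sus scrofa
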