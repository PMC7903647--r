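taxon_id	S1	S2	S3	S4	S5	S6
t1	3000	2000	3000	2500	2600	5000
t2	1500	1500	2000	1500	1500	4000
t3	1000	600	1500	700	700	2000
t4	400	400	500	300	300	900
s1	100	0	0	0	0	0
s2	0	0	0	0	0	100
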