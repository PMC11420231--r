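sample_id	AMELOGENIN-Y1	AMELOGENIN-Y2	AMELOGENIN-Y3	AMELOGENIN-X1	AMELOGENIN-X2
Panoria 1	0	0	0	6.7E7	3.9E7
Panoria 2	0	0	0	4.0E7	2.3E7
Panoria 3	6.6E7	13.4E7	1.7E7	10.5E7	5.4E7
Panoria 4	0	4.1E6	0	20.1E7	9.5E7
Panoria 5	0	7.8E6	0	38.9E7	20.4E7
Panoria 6	0	0	0	4.5E7	2.3E7
Panoria 7	0	0	0	2.4E7	1.4E7
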