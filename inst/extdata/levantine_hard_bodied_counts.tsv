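site	taxon_group	count
HS54	Nematoda	7168
HS54	Copepoda	1314
HS54	Polychaeta	482
HS54	Isopoda	43
HS54	Ostracoda	26
HS54	Cumacea	2
HS54	Mollusca	2
HS122	Nematoda	3548
HS122	Copepoda	544
HS122	Polychaeta	166
HS122	Isopoda	21
HS122	Ostracoda	5
HS122	Cumacea	8
HS122	Mollusca	2
HS394	Nematoda	13744
HS394	Copepoda	473
HS394	Polychaeta	174
HS394	Isopoda	4
HS394	Ostracoda	2
HS394	Cumacea	2
HS394	Mollusca	10
HS771	Nematoda	5452
HS771	Copepoda	133
HS771	Polychaeta	169
HS771	Isopoda	22
HS771	Cumacea	1
HS771	Mollusca	5
HS1134	Nematoda	716
HS1134	Copepoda	30
HS1134	Polychaeta	40
HS1418	Nematoda	46
HS1418	Polychaeta	3
TA76	Nematoda	9060
TA76	Copepoda	1168
TA76	Polychaeta	282
TA76	Isopoda	68
TA76	Ostracoda	11
TA154	Nematoda	4949
TA154	Copepoda	774
TA154	Polychaeta	129
TA154	Isopoda	14
TA154	Ostracoda	4
TA154	Cumacea	8
TA401	Nematoda	3113
TA401	Copepoda	129
TA401	Polychaeta	134
TA401	Isopoda	4
TA941	Nematoda	868
TA941	Copepoda	295
TA941	Polychaeta	34
TA941	Ostracoda	1
TA1173	Nematoda	403
TA1173	Copepoda	118
TA1173	Polychaeta	14
TA1173	Cumacea	1
TA1400	Nematoda	241
TA1400	Copepoda	51
TA1400	Polychaeta	1
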