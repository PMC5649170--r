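strain	group	tnp_count	size_mbp	origin
Synechococcus sp. CB0101	coastal	15	2.7	Chesapeake Bay
Synechococcus sp. CB0205	coastal	9	2.4	Chesapeake Bay
Synechococcus sp. RS9917	coastal	22	2.6	Red Sea
Synechococcus sp. WH5701	coastal	50	3.0	Long Island Sound
Synechococcus sp. BL107	open_ocean	0	2.3	Blanes Bay, Mediterranean Sea
Synechococcus sp. CC9311	open_ocean	0	2.6	California Current
Synechococcus sp. CC9902	open_ocean	0	2.2	California Current
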