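chr9	2015342	2193624	SMARCA2
chr9	4985033	5128183	JAK2
chr9	5450503	5470567	CD274
chr9	8314246	10612723	PTPRD
chr9	20341669	20622499	MLLT3
chr9	21060000	21480000	IFN_cluster
chr9	21802635	21941115	MTAP
chr9	21967751	21995300	CDKN2A
chr9	22002902	22009280	CDKN2B
chr9	36833272	37034103	PAX5
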