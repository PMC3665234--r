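gene	pdb	protein_name	compound	score
ESR1	1R5K	Estrogen receptor	corydaline	-6.99
DRD3	3PBL	D(3) dopamine receptor	corydaline	-6.53
CHRM2	3UON	Muscarinic acetylcholine receptor M2	corydaline	-6.33
CHRM3	4DAJ	Muscarinic acetylcholine receptor M3	corydaline	-6.28
CRYZ	1YB5	Quinone oxidoreductase	oxypeucedanin	-5.59
TOP2A	1ZXN	DNA topoisomerase 2-alpha	oxypeucedanin_M1	-5.79
VKORC1	3KP9	Vitamin K epoxide reductase complex subunit 1	byakangelicin	-6.04
ESR2	1QKM	Estrogen receptor beta	alpha-allocryptopine	-6.13
ACE	1UZF	Angiotensin-converting enzyme	tetrahydroberberine	-5.69
ADRA1A	3SN6	Alpha-1A adrenergic receptor	tetrahydropalmatine	-5.97
OPRK1	4DJH	Kappa-type opioid receptor	tetrahydropalmatine	-5.57
HRH1	3RZE	Histamine H1 receptor	tetrahydropalmatine	-5.52
ADRA2A	3RFM	Alpha-2A adrenergic receptor	tetrahydropalmatine_M2	-6.90
ABCC8	2BBO	ATP-binding cassette transporter subfamily C member 8	protopine_M1	-5.52
KCNJ8	3HFC	ATP-sensitive inward rectifier potassium channel 8	protopine_M1	-5.74
BCHE	2WIL	Cholinesterase	protopine_M1	-5.42
RNASE3	1DYT	Eosinophil cationic protein	protopine_M1	-5.21
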