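id	rt_min	mz	formula	change	parent	source
M1	4.1880	342.1333	C19H19NO5	-CH2+H2	protopine	plasma
M2	9.08278	342.1691	C20H23NO4	-CH2	tetrahydropalmatine	plasma
M3	10.6147	342.1695	C20H23NO4	-CH2	tetrahydropalmatine	plasma;csf
M4	21.8366	301.0715	C16H12O6	+O-H2	oxypeucedanin	plasma
M5	5.21887	326.1384	C19H19NO4	-CH2	tetrahydroberberine	plasma;csf
M6	8.0093	326.1386	C19H19NO4	-CH2	tetrahydroberberine	plasma
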