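id	name	source_herb	kind	parent_id	formula
1	imperatorin	Radix_angelicae_dahuricae	prototype		C16H14O4
2	byakangelicol	Radix_angelicae_dahuricae	prototype		C17H16O6
3	byakangelicin	Radix_angelicae_dahuricae	prototype		C17H18O7
4	bergapten	Radix_angelicae_dahuricae	prototype		C12H8O4
5	psoralen	Radix_angelicae_dahuricae	prototype		C11H6O3
6	xanthotoxin	Radix_angelicae_dahuricae	prototype		C12H8O4
7	coptisine	Rhizoma_corydalis	prototype		C19H14NO4
8	alpha-allocryptopine	Rhizoma_corydalis	prototype		C21H23NO5
9	isoimperatorin	Radix_angelicae_dahuricae	prototype		C16H14O4
10	oxypeucedanin	Radix_angelicae_dahuricae	prototype		C16H14O5
11	corydaline	Rhizoma_corydalis	prototype		C22H27NO4
12	tetrahydropalmatine	Rhizoma_corydalis	prototype		C21H25NO4
13	tetrahydroberberine	Rhizoma_corydalis	prototype		C20H21NO4
14	berberine	Rhizoma_corydalis	prototype		C20H18NO4
15	protopine	Rhizoma_corydalis	prototype		C20H19NO5
16	oxypeucedanin_M1	Radix_angelicae_dahuricae	metabolite	10	C16H12O6
17	tetrahydroberberine_M1	Rhizoma_corydalis	metabolite	13	C19H19NO4
18	tetrahydroberberine_M2	Rhizoma_corydalis	metabolite	13	C19H19NO4
19	tetrahydropalmatine_M1	Rhizoma_corydalis	metabolite	12	C20H23NO4
20	tetrahydropalmatine_M2	Rhizoma_corydalis	metabolite	12	C20H23NO4
21	protopine_M1	Rhizoma_corydalis	metabolite	15	C19H19NO5
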