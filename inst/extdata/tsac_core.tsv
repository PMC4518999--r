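#! thermoflux-model-tsv 1
#! compartments {"c":"cytosol","e":"extracellular"}
#! objective BIOMASS
#! metabolite_formula CO2[c] CO2
#! metabolite_formula CO2[e] CO2
#! metabolite_formula etoh[c] C2H6O
#! metabolite_formula etoh[e] C2H6O
#! metabolite_formula glc-D[c] C6H12O6
#! metabolite_formula glc-D[e] C6H12O6
#! metabolite_formula H2[c] H2
#! metabolite_formula H2[e] H2
#! metabolite_formula H2O[c] H2O
#! metabolite_formula H2O[e] H2O
id	name	formula	lb	ub	gene_rule
EX_glc	D-glucose exchange	glc-D[e] -> 	-10	0	
EX_etoh	ethanol exchange	etoh[e] -> 	0	1000	
EX_ac	acetate exchange	ac[e] -> 	0	1000	
EX_lac	L-lactate exchange	lac-L[e] -> 	0	1000	
EX_h2	hydrogen exchange	H2[e] -> 	0	1000	
EX_co2	CO2 exchange	CO2[e] -> 	0	1000	
EX_pyr	pyruvate exchange	pyr[e] -> 	0	1000	
EX_nh4	ammonium exchange	NH4[e] -> 	-1000	0	
EX_h2o	water exchange	H2O[e] <=> 	-1000	1000	
EX_h	proton exchange	H[e] <=> 	-1000	1000	
GLCt	glucose transport	glc-D[e] -> glc-D[c]	0	1000	g_glct
ETOHt	ethanol transport	etoh[c] -> etoh[e]	0	1000	
ACt	acetate transport	ac[c] -> ac[e]	0	1000	
LACt	lactate transport	lac-L[c] -> lac-L[e]	0	1000	
H2t	hydrogen transport	H2[c] -> H2[e]	0	1000	
CO2t	CO2 transport	CO2[c] -> CO2[e]	0	1000	
PYRt	pyruvate efflux	pyr[c] -> pyr[e]	0	1000	
NH4t	ammonium transport	NH4[e] -> NH4[c]	0	1000	
H2Ot	water transport	H2O[c] <=> H2O[e]	-1000	1000	
Ht	proton transport	H[c] <=> H[e]	-1000	1000	
GLYC	glycolysis (lumped)	glc-D[c] + 2 ADP[c] + 2 Pi[c] + 2 NAD[c] -> 2 pyr[c] + 2 ATP[c] + 2 NADH[c] + 2 H[c] + 2 H2O[c]	0	1000	g_glyc
POR	pyruvate:ferredoxin oxidoreductase	pyr[c] + CoA[c] + Fdox[c] -> AcCoA[c] + CO2[c] + Fdred[c]	0	1000	g_por
LDH_L	L-lactate dehydrogenase	lac-L[c] + NAD[c] <=> NADH[c] + H[c] + pyr[c]	-1000	1000	Tsac_0179
PTAr	phosphotransacetylase	Pi[c] + AcCoA[c] <=> CoA[c] + actp[c]	-1000	1000	Tsac_1744
ACK	acetate kinase	actp[c] + ADP[c] -> ac[c] + ATP[c]	0	1000	g_ack
ACALD	acetaldehyde dehydrogenase	AcCoA[c] + NADH[c] + H[c] <=> acald[c] + CoA[c] + NAD[c]	-1000	1000	g_aldh
ALCD	alcohol dehydrogenase	acald[c] + NADH[c] + H[c] <=> etoh[c] + NAD[c]	-1000	1000	g_adh
HFS	ferredoxin hydrogenase (hfs)	Fdred[c] + 2 H[c] <=> Fdox[c] + H2[c]	-1000	1000	Tsac_1550 & Tsac_1551 & Tsac_1552 & Tsac_1553
ECH	energy-conserving hydrogenase	Fdred[c] + 2 H[c] <=> Fdox[c] + H2[c]	-1000	1000	g_ech
BIFH2	bifurcating hydrogenase	Fdred[c] + NADH[c] + 3 H[c] <=> 2 H2[c] + Fdox[c] + NAD[c]	-1000	1000	g_bifh2
NADH2	NADH hydrogenase	NADH[c] + H[c] <=> H2[c] + NAD[c]	-1000	1000	g_nadh2
RNF	ferredoxin:NAD oxidoreductase	Fdred[c] + NAD[c] + H[c] -> Fdox[c] + NADH[c]	0	1000	g_rnf
THD	transhydrogenase	NADH[c] + NADP[c] -> NAD[c] + NADPH[c]	0	1000	g_thd
AKGS	alpha-ketoglutarate synthesis (lumped)	pyr[c] + AcCoA[c] + NADP[c] + H2O[c] -> akg[c] + CoA[c] + NADPH[c] + 2 H[c]	0	1000	g_akgs
GLNS	glutamine synthetase	glu-L[c] + ATP[c] + NH4[c] -> ADP[c] + Pi[c] + H[c] + gln-L[c]	0	1000	Tsac_2029
GLUDy	glutamate dehydrogenase (NADP)	NADP[c] + H2O[c] + glu-L[c] <=> H[c] + NADPH[c] + NH4[c] + akg[c]	-1000	1000	Tsac_2172
GLUSy	glutamate synthase (NADPH)	H[c] + NADPH[c] + gln-L[c] + akg[c] -> NADP[c] + 2 glu-L[c]	0	1000	Tsac_1234
ATPM	ATP maintenance	ATP[c] + H2O[c] -> ADP[c] + Pi[c] + H[c]	2	1000	
BIOMASS	biomass synthesis	4 pyr[c] + AcCoA[c] + 60 ATP[c] + 18 NADPH[c] + 0.6 glu-L[c] + 0.2 gln-L[c] + 42 H2O[c] -> 60 ADP[c] + 60 Pi[c] + 18 NADP[c] + CoA[c] + 78 H[c]	0	1000	
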