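# nanofate thermodynamic database, v1
# Aqueous formation constants at 25 C, zero ionic strength (MINTEQ/NIST-family
# critical compilations). Stoichiometry is written over components as
# component:coefficient pairs, semicolon-separated; H+ coefficients express
# proton gain/loss relative to the component basis (NH4+, CO3-2, ...).
species	charge	log_k	ref_temp_C	stoichiometry
OH-	-1	-13.997	25	H+:-1
NH3	0	-9.244	25	NH4+:1;H+:-1
HCO3-	-1	10.329	25	CO3-2:1;H+:1
H2CO3*	0	16.681	25	CO3-2:1;H+:2
HSO4-	-1	1.990	25	SO4-2:1;H+:1
HNO2	0	3.220	25	NO2-:1;H+:1
NaCl	0	-0.300	25	Na+:1;Cl-:1
NaSO4-	-1	0.730	25	Na+:1;SO4-2:1
NaHCO3	0	10.079	25	Na+:1;CO3-2:1;H+:1
NaCO3-	-1	1.270	25	Na+:1;CO3-2:1
KSO4-	-1	0.850	25	K+:1;SO4-2:1
NH4SO4-	-1	1.030	25	NH4+:1;SO4-2:1
MgSO4	0	2.370	25	Mg+2:1;SO4-2:1
MgCl+	1	0.600	25	Mg+2:1;Cl-:1
MgCO3	0	2.920	25	Mg+2:1;CO3-2:1
MgHCO3+	1	11.400	25	Mg+2:1;CO3-2:1;H+:1
MgOH+	1	-11.440	25	Mg+2:1;H+:-1
CaSO4	0	2.360	25	Ca+2:1;SO4-2:1
CaCO3	0	3.220	25	Ca+2:1;CO3-2:1
CaHCO3+	1	11.430	25	Ca+2:1;CO3-2:1;H+:1
CaOH+	1	-12.700	25	Ca+2:1;H+:-1
AgCl	0	3.310	25	Ag+:1;Cl-:1
AgCl2-	-1	5.250	25	Ag+:1;Cl-:2
AgCl3-2	-2	5.200	25	Ag+:1;Cl-:3
AgNH3+	1	-5.934	25	Ag+:1;NH4+:1;H+:-1
Ag(NH3)2+	1	-11.268	25	Ag+:1;NH4+:2;H+:-2
AgOH	0	-12.000	25	Ag+:1;H+:-1
Ag(OH)2-	-1	-24.000	25	Ag+:1;H+:-2
AgNO2	0	2.220	25	Ag+:1;NO2-:1
AgSO4-	-1	1.290	25	Ag+:1;SO4-2:1
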