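id,name,smiles,rate_q,rate_r,is_test_q,is_test_r
phenyl_acetate,Phenyl acetate,CC(=O)Oc1ccccc1,100,100,FALSE,FALSE
paraoxon,Paraoxon,CCOP(=O)(OCC)Oc1ccc(cc1)[N+](=O)[O-],0.13,0.99,FALSE,FALSE
coumaranone,2-Coumaranone,O=C1Cc2ccccc2O1,18.3,13.5,FALSE,FALSE
dihydrocoumarin,Dihydrocoumarin,O=C1CCc2ccccc2O1,14.3,17.0,TRUE,TRUE
homogentisic_lactone,Homogentisic acid lactone,O=C1Cc2cc(O)ccc2O1,44.0,49.7,FALSE,FALSE
gbl,gamma-Butyrolactone,O=C1CCCO1,2.46,9.05,TRUE,FALSE
abr_gbl,alpha-Bromo-gamma-butyrolactone,BrC1CCOC1=O,47.2,40.8,FALSE,FALSE
s_a_oh_gbl,S-alpha-Hydroxy-gamma-butyrolactone,O[C@H]1CCOC1=O,8.14,19.6,FALSE,FALSE
s_b_oh_gbl,S-beta-Hydroxy-gamma-butyrolactone,O=C1C[C@H](O)CO1,0.60,0.76,TRUE,FALSE
gvl,gamma-Valerolactone,CC1CCC(=O)O1,7.28,6.97,TRUE,FALSE
r_hm_furanone,R-Dihydro-5-(hydroxymethyl)-2(3H)-furanone,OC[C@H]1CCC(=O)O1,1.23,3.29,FALSE,FALSE
g_decanolactone,gamma-Decanolactone,CCCCCCC1CCC(=O)O1,12.4,19.0,FALSE,FALSE
undecano_g_lactone,Undecano-gamma-lactone,CCCCCCCC1CCC(=O)O1,11.8,12.7,FALSE,FALSE
angelicalactone,alpha-Angelicolactone,CC1=CCC(=O)O1,19.9,14.8,FALSE,FALSE
bbl,beta-Butyrolactone,CC1CC(=O)O1,3.83,7.53,FALSE,FALSE
dvl,delta-Valerolactone,O=C1CCCCO1,75.4,71.0,FALSE,FALSE
d_decanolactone,delta-Decanolactone,CCCCCC1CCCC(=O)O1,23.8,28.2,FALSE,FALSE
undecanoic_d_lactone,Undecanoic-delta-lactone,CCCCCCC1CCCC(=O)O1,27.5,32.8,TRUE,TRUE
d_dodecanolactone,delta-Dodecanolactone,CCCCCCCC1CCCC(=O)O1,9.65,12.8,FALSE,FALSE
caprolactone,epsilon-Caprolactone,O=C1CCCCCO1,14.8,25.7,FALSE,FALSE
oxabicyclooctenone,Oxabicyclooctenone,O=C1OC2CCC1C=C2,1.67,2.92,FALSE,FALSE
g_thiobutyrolactone,gamma-Thiobutyrolactone,O=C1CCCS1,0.04,0.11,FALSE,FALSE
htl,Homocysteine thiolactone,NC1CCSC1=O,0.004,0.009,FALSE,FALSE
propylene_carbonate,Propylene carbonate,CC1COC(=O)O1,5.02,8.80,TRUE,FALSE
propenyloxymethyl_dioxolanone,"4-(1-Propenyloxymethyl)-1,3-dioxolan-2-one",CC=COCC1COC(=O)O1,2.23,2.52,FALSE,FALSE
methyldioxolyl_benzenesulfonate,"4-[(5-methyl-2-oxo-1,3-dioxol-4-yl)methylthio]benzenesulfonate",CC1=C(CSc2ccc(cc2)S(=O)(=O)O)OC(=O)O1,1.46,9.65,FALSE,TRUE
sarin,Sarin,CC(C)OP(C)(=O)F,0.14,0.02,FALSE,FALSE
soman,Soman,CC(C(C)(C)C)OP(C)(=O)F,0.85,0.55,FALSE,TRUE
diazoxon,Diazoxon,CCOP(=O)(OCC)Oc1cc(C)nc(n1)C(C)C,4.88,4.45,FALSE,TRUE
chlorpyrifos_oxon,Chlorpyrifos oxon,CCOP(=O)(OCC)Oc1nc(Cl)c(Cl)cc1Cl,2.97,5.40,FALSE,FALSE
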