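metabolite_id	name	formula	monoisotopic_mass	pathway_ids
nicotinic_acid	Nicotinic acid	C6H5NO2	123.032028	vitamin_b3
nicotinamide	Nicotinamide	C6H6N2O	122.048013	vitamin_b3
n1_methyl_4_pyridone_5_carboxamide	N1-methyl-4-pyridone-5-carboxamide	C7H8N2O2	152.058578	vitamin_b3
n1_methyl_2_pyridone_5_carboxamide	N1-methyl-2-pyridone-5-carboxamide	C7H8N2O2	152.058578	vitamin_b3
nicotinuric_acid	Nicotinuric acid	C8H8N2O3	180.053492	vitamin_b3
trigonelline	Trigonelline	C7H7NO2	137.047678	vitamin_b3
quinolinic_acid	Quinolinic acid	C7H5NO4	167.021858	vitamin_b3
nicotinamide_n_oxide	Nicotinamide N-oxide	C6H6N2O2	138.042927	vitamin_b3
hydroxynicotinic_acid_6	6-Hydroxynicotinic acid	C6H5NO3	139.026943	vitamin_b3
nad	Nicotinamide adenine dinucleotide	C21H27N7O14P2	663.109122	vitamin_b3
arachidonic_acid	Arachidonic acid	C20H32O2	304.240230	arachidonic_acid
pge2	Prostaglandin E2	C20H32O5	352.224974	arachidonic_acid
pgd2	Prostaglandin D2	C20H32O5	352.224974	arachidonic_acid
pgf2a	Prostaglandin F2alpha	C20H34O5	354.240624	arachidonic_acid
txb2	Thromboxane B2	C20H34O6	370.235539	arachidonic_acid
ltb4	Leukotriene B4	C20H32O4	336.230060	arachidonic_acid
lta4	Leukotriene A4	C20H30O3	318.219495	arachidonic_acid
hete_5	5-HETE	C20H32O3	320.235145	arachidonic_acid
hete_12	12-HETE	C20H32O3	320.235145	arachidonic_acid
hete_15	15-HETE	C20H32O3	320.235145	arachidonic_acid
pge1	Prostaglandin E1	C20H34O5	354.240624	arachidonic_acid
pgj2	Prostaglandin J2	C20H30O4	334.214409	arachidonic_acid
methionine	L-Methionine	C5H11NO2S	149.051049	methionine_cysteine
cysteine	L-Cysteine	C3H7NO2S	121.019749	methionine_cysteine
cystine	L-Cystine	C6H12N2O4S2	240.023848	methionine_cysteine
homocysteine	L-Homocysteine	C4H9NO2S	135.035399	methionine_cysteine
cystathionine	L-Cystathionine	C7H14N2O4S	222.067428	methionine_cysteine
s_adenosylhomocysteine	S-Adenosylhomocysteine	C14H20N6O5S	384.121588	methionine_cysteine
taurine	Taurine	C2H7NO3S	125.014664	methionine_cysteine
hypotaurine	Hypotaurine	C2H7NO2S	109.019749	methionine_cysteine
glutathione	Glutathione	C10H17N3O6S	307.083806	methionine_cysteine
serine	L-Serine	C3H7NO3	105.042593	methionine_cysteine
methionine_sulfoxide	Methionine sulfoxide	C5H11NO3S	165.045964	methionine_cysteine
cysteic_acid	Cysteic acid	C3H7NO5S	169.004493	methionine_cysteine
hypoxanthine	Hypoxanthine	C5H4N4O	136.038511	purine
xanthine	Xanthine	C5H4N4O2	152.033425	purine
uric_acid	Uric acid	C5H4N4O3	168.028340	purine
inosine	Inosine	C10H12N4O5	268.080770	purine
adenosine	Adenosine	C10H13N5O4	267.096754	purine;methionine_cysteine
guanosine	Guanosine	C10H13N5O5	283.091669	purine
adenine	Adenine	C5H5N5	135.054495	purine
guanine	Guanine	C5H5N5O	151.049410	purine
amp	Adenosine monophosphate	C10H14N5O7P	347.063084	purine
gmp	Guanosine monophosphate	C10H14N5O8P	363.057999	purine
imp	Inosine monophosphate	C10H13N4O8P	348.047100	purine
xanthosine	Xanthosine	C10H12N4O6	284.075684	purine
deoxyadenosine	Deoxyadenosine	C10H13N5O3	251.101839	purine
deoxyguanosine	Deoxyguanosine	C10H13N5O4	267.096754	purine
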