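drug_name	rxcui	atc_code	atc_name	estimate_drug_cost_per_day	UMLS_CUI	DrugBankID
acetaminophen	900001	N02BE01	ANALGESICS	0.05	C900001	DB90001
alprazolam	900002	N05BA12	PSYCHOLEPTICS	0.12	C900002	DB90002
amlodipine	900003	C08CA01	CALCIUM CHANNEL BLOCKERS	0.10	C900003	DB90003
amoxicillin	900004	J01CA04	ANTIBACTERIALS FOR SYSTEMIC USE	0.40	C900004	DB90004
atorvastatin	900005	C10AA05	LIPID MODIFYING AGENTS	0.35	C900005	DB90005
azithromycin	900006	J01FA10	ANTIBACTERIALS FOR SYSTEMIC USE	1.60	C900006	DB90006
ciprofloxacin	900007	J01MA02	ANTIBACTERIALS FOR SYSTEMIC USE	0.80	C900007	DB90007
hydrochlorothiazide	900008	C03AA03	DIURETICS	0.07	C900008	DB90008
hydrocodone	900009	R05DA03	COUGH AND COLD PREPARATIONS	0.50	C900009	DB90009
ibuprofen	900010	M01AE01	ANTIINFLAMMATORY AND ANTIRHEUMATIC PRODUCTS	0.15	C900010	DB90010
levothyroxine	900011	H03AA01	THYROID THERAPY	0.25	C900011	DB90011
lisinopril	900012	C09AA03	AGENTS ACTING ON THE RENIN-ANGIOTENSIN SYSTEM	0.08	C900012	DB90012
metformin	900013	A10BA02	DRUGS USED IN DIABETES	0.15	C900013	DB90013
metoprolol	900014	C07AB02	BETA BLOCKING AGENTS	0.09	C900014	DB90014
omeprazole	900015	A02BC01	DRUGS FOR ACID RELATED DISORDERS	0.20	C900015	DB90015
oxycodone	900016	N02AA05	ANALGESICS	0.90	C900016	DB90016
prednisone	900017	H02AB07	CORTICOSTEROIDS FOR SYSTEMIC USE	0.30	C900017	DB90017
sertraline	900018	N06AB06	PSYCHOANALEPTICS	0.18	C900018	DB90018
simvastatin	900019	C10AA01	LIPID MODIFYING AGENTS	0.12	C900019	DB90019
warfarin	900020	B01AA03	ANTITHROMBOTIC AGENTS	0.11	C900020	DB90020
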