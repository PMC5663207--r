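atc_class	atc_class_name
A02	DRUGS FOR ACID RELATED DISORDERS
A10	DRUGS USED IN DIABETES
B01	ANTITHROMBOTIC AGENTS
C03	DIURETICS
C07	BETA BLOCKING AGENTS
C08	CALCIUM CHANNEL BLOCKERS
C09	AGENTS ACTING ON THE RENIN-ANGIOTENSIN SYSTEM
C10	LIPID MODIFYING AGENTS
H02	CORTICOSTEROIDS FOR SYSTEMIC USE
H03	THYROID THERAPY
J01	ANTIBACTERIALS FOR SYSTEMIC USE
M01	ANTIINFLAMMATORY AND ANTIRHEUMATIC PRODUCTS
N02	ANALGESICS
N05	PSYCHOLEPTICS
N06	PSYCHOANALEPTICS
R05	COUGH AND COLD PREPARATIONS
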