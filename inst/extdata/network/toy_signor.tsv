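entity_a	entity_b	effect	mechanism
KSR1	STK4	binding	complex formation
STK4	LATS1	up-regulates activity	phosphorylation
STK4	LATS2	up-regulates activity	phosphorylation
LATS1	YAP1	down-regulates activity	phosphorylation
LATS2	YAP1	down-regulates activity	phosphorylation
KSR1	MAP2K1	up-regulates activity	scaffolding
MAP2K1	MAPK1	up-regulates activity	phosphorylation
MAPK1	YAP1	down-regulates	phosphorylation
KSR1	RAF1	up-regulates activity	scaffolding
RHOA	LATS1	down-regulates activity	unknown
RHOA	LIMK1	up-regulates activity	binding
LIMK1	CFL1	down-regulates activity	phosphorylation
AMOT	YAP1	down-regulates quantity	sequestration
YAP1	CCN1	up-regulates quantity by expression	transcriptional regulation
YAP1	CCN2	up-regulates quantity by expression	transcriptional regulation
STK3	LATS1	up-regulates activity	phosphorylation
PXN	RHOA	up-regulates activity	unknown
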