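KEGG_METABOLISM_TOY	toy KEGG-style metabolic pathway	MET01	MET02	MET03	MET04	MET05	MET06	MET07	MET08	MET09	MET10	MET11	MET12	MET13	MET14	MET15	MET16	MET17	MET18	MET19	MET20	MET21	MET22	MET23	MET24	MET25	MET26	MET27	MET28	MET29	MET30
GO_PROTEOLYSIS_TOY	toy GO proteolysis process	PRT01	PRT02	PRT03	PRT04	PRT05	PRT06	PRT07	PRT08	PRT09	PRT10	PRT11	PRT12	PRT13	PRT14	PRT15	PRT16	PRT17	PRT18	PRT19	PRT20	PRT21	PRT22	PRT23	PRT24	PRT25	PRT26	PRT27	PRT28	PRT29	PRT30
GO_DNA_REPAIR_TOY	toy GO DNA repair process	DNA01	DNA02	DNA03	DNA04	DNA05	DNA06	DNA07	DNA08	DNA09	DNA10	DNA11	DNA12	DNA13	DNA14	DNA15	DNA16	DNA17	DNA18	DNA19	DNA20	DNA21	DNA22	DNA23	DNA24	DNA25	DNA26	DNA27	DNA28	DNA29	DNA30
KEGG_KINASE_SIGNALING_TOY	toy KEGG-style kinase signalling	KIN01	KIN02	KIN03	KIN04	KIN05	KIN06	KIN07	KIN08	KIN09	KIN10	KIN11	KIN12	KIN13	KIN14	KIN15	KIN16	KIN17	KIN18	KIN19	KIN20	KIN21	KIN22	KIN23	KIN24	KIN25	KIN26	KIN27	KIN28	KIN29	KIN30
GO_CHROMATIN_MODIFICATION_TOY	toy GO chromatin modification	EPI01	EPI02	EPI03	EPI04	EPI05	EPI06	EPI07	EPI08	EPI09	EPI10	EPI11	EPI12	EPI13	EPI14	EPI15	EPI16	EPI17	EPI18	EPI19	EPI20	EPI21	EPI22	EPI23	EPI24	EPI25	EPI26	EPI27	EPI28	EPI29	EPI30
GO_MICROTUBULE_TOY	toy GO microtubule process	MTU01	MTU02	MTU03	MTU04	MTU05	MTU06	MTU07	MTU08	MTU09	MTU10	MTU11	MTU12	MTU13	MTU14	MTU15	MTU16	MTU17	MTU18	MTU19	MTU20	MTU21	MTU22	MTU23	MTU24	MTU25	MTU26	MTU27	MTU28	MTU29	MTU30
GO_VESICLE_TRANSPORT_TOY	toy GO vesicle-mediated transport	VES01	VES02	VES03	VES04	VES05	VES06	VES07	VES08	VES09	VES10	VES11	VES12	VES13	VES14	VES15	VES16	VES17	VES18	VES19	VES20	VES21	VES22	VES23	VES24	VES25
GO_ALZHEIMER_LIKE_TOY	toy Alzheimer-like process	ALZ01	ALZ02	ALZ03	ALZ04	ALZ05	ALZ06	ALZ07	ALZ08	ALZ09	ALZ10	ALZ11	ALZ12	ALZ13	ALZ14	ALZ15	ALZ16	ALZ17	ALZ18	ALZ19	ALZ20	MET01	MET02	MET03	MET04	MET05	PRT01	PRT02	PRT03	PRT04	PRT05	DNA01	DNA02	DNA03	DNA04	DNA05
GO_MIXED_HOUSEKEEPING_TOY	toy housekeeping mixture	BGD01	BGD02	BGD03	BGD04	BGD05	BGD06	BGD07	BGD08	BGD09	BGD10	BGD11	BGD12	BGD13	BGD14	BGD15	VES01	VES02	VES03	VES04	VES05	KIN01	KIN02	KIN03	KIN04	KIN05
GO_STRESS_RESPONSE_TOY	toy stress response	BGD16	BGD17	BGD18	BGD19	BGD20	BGD21	BGD22	BGD23	BGD24	BGD25	BGD26	BGD27	BGD28	BGD29	BGD30	EPI01	EPI02	EPI03	EPI04	EPI05	MTU01	MTU02	MTU03	MTU04	MTU05
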