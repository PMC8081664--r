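lineage	alias	universal
mammals	OXT	OT
mammals	Oxy	OT
mammals	NPI	OT
mammals	AVP	VT
mammals	ARVP	VT
mammals	AVRP	VT
mammals	Vp	VT
mammals	Vsp	VT
mammals	NP2	VT
mammals	OXTR	OTR
mammals	AVPR1A	VTR1A
mammals	V1aR	VTR1A
mammals	V1A	VTR1A
mammals	AVPR1B	VTR1B
mammals	AVPR3	VTR1B
mammals	V1bR	VTR1B
mammals	V1BR	VTR1B
mammals	V3	VTR1B
mammals	AVPR2	VTR2C
mammals	V2R	VTR2C
mammals	VPV2R	VTR2C
birds	MT	OT
birds	MST	OT
birds	VT3	OTR
birds	MTR	OTR
birds	VT4	VTR1A
birds	VT4R	VTR1A
birds	VT2	VTR1B
birds	AVT2R	VTR1B
birds	VT1	VTR2A
turtles_crocodiles	MT	OT
turtles_crocodiles	MST	OT
turtles_crocodiles	OXTR	OTR
turtles_crocodiles	Avpr1	VTR1A
turtles_crocodiles	VasR	VTR1A
turtles_crocodiles	Avpr2.2	VTR2A
frogs	MT	OT
frogs	MST	OT
frogs	MesoR	OTR
frogs	OXTR	OTR
frogs	Avpr1aa	VTR1A
frogs	Avpr1ab	VTR1A
frogs	V2C	VTR2A
frogs	V2bR2	VTR2A
frogs	Avpr2.2	VTR2A
frogs	V2L	VTR2A
fish	IT	OT
fish	IST	OT
fish	avpl	VT
fish	vsnp	VT
fish	ITR	OTR
fish	itr2	OTR
fish	OXTR	OTR
fish	itnpr-like-2	OTR
fish	V2C	VTR2A
fish	V2bR2	VTR2A
fish	V2B	VTR2B
fish	V2BR1	VTR2B
fish	V2RI	VTR2B
fish	OTRI	VTR2B
fish	nft	VTR2B
fish	avpr2	VTR2B
fish	AVPR4	VTR2B
fish	Avpr2bb	VTR2C
fish	avpr2a	VTR2C
fish	AVPR2A	VTR2C
sharks	Valitocin	OT
sharks	Aspargtocin	OT
sharks	Glumitocin	OT
sharks	Phenypresin	VT
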