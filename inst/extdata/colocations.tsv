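lineage	a	b	same_chrom
lampreys	OTR	VTR2B	TRUE
coelacanth	OTR	VTR2B	TRUE
holostei	OTR	VTR2B	TRUE
teleostei	OTR	VTR2B	TRUE
sharks	OTR	VTR2B	TRUE
lampreys	VTR1A	VTR2A	TRUE
birds	VTR1A	VTR2A	TRUE
turtles_crocodiles	VTR1A	VTR2A	TRUE
frogs	VTR1A	VTR2A	TRUE
coelacanth	VTR1A	VTR2A	TRUE
holostei	VTR1A	VTR2A	TRUE
sharks	VTR1A	VTR2A	TRUE
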