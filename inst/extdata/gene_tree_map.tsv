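leaf	species	orthogroup
lamprey_OTR	lampreys	OTR
human_OTR	mammals	OTR
chicken_OTR	birds	OTR
frog_OTR	frogs	OTR
lamprey_VTR1A	lampreys	VTR1A
human_VTR1A	mammals	VTR1A
chicken_VTR1A	birds	VTR1A
frog_VTR1A	frogs	VTR1A
human_VTR1B	mammals	VTR1B
chicken_VTR1B	birds	VTR1B
lamprey_VTR2A	lampreys	VTR2A
chicken_VTR2A	birds	VTR2A
frog_VTR2A	frogs	VTR2A
lamprey_VTR2B	lampreys	VTR2B
gar_VTR2B	holostei	VTR2B
teleost_VTR2B	teleostei	VTR2B
human_VTR2C	mammals	VTR2C
frog_VTR2C	frogs	VTR2C
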