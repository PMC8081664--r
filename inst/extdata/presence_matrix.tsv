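gene	mammals	birds	turtles_crocodiles	frogs	coelacanth	holostei	teleostei	sharks	lampreys	hagfishes
OT	1	1	1	1	1	1	1	1	.	.
VT	1	1	1	1	1	1	1	1	1	1
OTR	1	1	1	1	1	1	1	1	1	.
VTR1A	1	1	1	1	1	1	1	1	1	.
VTR1B	1	1	1	1	1	0	0	1	.	.
VTR2A	0	1	1	1	1	1	0	1	1	.
VTR2B	0	0	0	0	1	1	1	1	1	.
VTR2C	1	0	1	1	1	1	1	.	.	.
VTR1	.	.	.	.	.	.	.	.	.	1
VTR2	.	.	.	.	.	.	.	.	.	1
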