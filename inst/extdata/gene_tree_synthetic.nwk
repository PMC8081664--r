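((amphioxus_VTRx1,amphioxus_VTRx2,amphioxus_VTRx3)100,(((lamprey_OTR,lamprey_VTR1A)72,((human_OTR,(chicken_OTR,frog_OTR)88)95,((human_VTR1A,(chicken_VTR1A,frog_VTR1A)90)93,(human_VTR1B,chicken_VTR1B)97)74)81)99,((lamprey_VTR2A,lamprey_VTR2B)73,((chicken_VTR2A,frog_VTR2A)91,((gar_VTR2B,teleost_VTR2B)89,(human_VTR2C,frog_VTR2C)86)70)78)96)55);
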