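#taxon,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19
willistoni,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
prosaltans,0,0,0,0,0,1,1,0,0,0,1,1,1,0,1,0,0,0,1
lusaltans,0,0,0,0,0,1,1,0,1,0,1,1,1,0,0,0,0,0,1
saltans,0,0,0,0,0,1,1,0,0,1,0,1,2,0,1,0,0,0,1
austrosaltans,0,0,0,0,0,1,1,1,0,0,1,1,1,0,1,0,0,0,1
sturtevanti,1,1,0,1,1,0,0,0,0,0,0,0,0,0,1,0,0,0,0
dacunhai,1,1,1,1,1,0,0,0,0,0,0,0,0,0,1,0,0,0,0
milleri,1,1,1,1,1,0,0,0,0,0,0,0,0,0,1,0,0,0,0
parasaltans,0,0,0,0,2,0,0,0,0,0,0,1,1,0,1,0,0,0,1
neocordata,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,1,1,0
emarginata,1,0,0,0,0,1,0,0,0,0,0,0,0,1,1,1,0,0,0
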