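species,c,h,o,n
glucose,6,12,6,0
ethanol,2,6,1,0
arabitol,5,12,5,0
succinate,4,6,4,0
co2,1,0,2,0
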