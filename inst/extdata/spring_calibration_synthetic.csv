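"spring","length_m","tension_N"
"tibial",0.13,3
"tibial",0.15,9
"tibial",0.18,18
"femoral",0.13,3
"femoral",0.15,6
"femoral",0.18,10.5
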