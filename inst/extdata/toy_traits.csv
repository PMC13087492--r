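"species_id","guild","length_mm","ctmax_c","trophic_group"
"f1","fish",300,32,"top"
"f2","fish",150,30,"mid"
"f3","fish",80,28,"low"
"f4","fish",450,26,"top"
"f5","fish",120,24,"mid"
"z1","zooplankton",0.4,35,"low"
"z2","zooplankton",1.2,33,"mid"
"z3","zooplankton",0.6,34,"low"
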