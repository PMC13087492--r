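"site_id","f1","f2","f3","f4","f5","z1","z2","z3"
"s1",1,1,0,0,1,1,0,1
"s2",1,1,1,0,0,1,1,0
"s3",1,0,1,1,0,1,1,1
"s4",1,0,0,1,0,0,1,0
"s5",0,0,1,1,0,1,0,1
"s6",0,0,0,1,1,1,0,0
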