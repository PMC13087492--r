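"site_id","lon","lat","temp_max","precip_total","lake_area"
"s1",-72,46,26,950,12
"s2",-71,48,24,980,5
"s3",-70.5,50,21,1010,48
"s4",-69.8,52.5,19,990,7
"s5",-69,55,16,1060,150
"s6",-68,58,14,1100,22
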