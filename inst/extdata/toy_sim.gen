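synthetic two-population SNP toy (simulated)
loc1
loc2
loc3
loc4
loc5
loc6
loc7
loc8
loc9
loc10
loc11
loc12
POP
ind1 , 001002 001001 002002 002002 001001 001001 002002 002002 002002 001002 001001 001001
ind2 , 001002 001002 002002 002002 001001 001001 002002 002002 002002 002002 001001 001001
ind3 , 002002 001001 001001 001002 001001 001001 001002 002002 001002 001001 001001 001001
ind4 , 002002 001001 001001 002002 001001 001001 002002 002002 002002 001002 001001 001001
ind5 , 002002 001001 002002 002002 001001 001001 001002 002002 002002 001001 001001 001001
ind6 , 002002 001002 001001 001002 001001 001001 002002 002002 002002 001002 001001 001001
ind7 , 002002 001002 001001 001002 001001 001001 001002 002002 002002 002002 001001 001001
ind8 , 002002 001001 002002 002002 001001 001001 001002 002002 002002 001001 001002 001001
ind9 , 002002 002002 001002 002002 001001 001002 001002 002002 001002 001001 001001 001001
ind10 , 002002 001002 001002 002002 001001 001001 001001 002002 001002 001001 001001 001001
ind11 , 002002 001001 001002 001001 001001 001001 002002 002002 002002 001002 001001 001001
ind12 , 002002 001001 001002 002002 001001 001001 001002 002002 002002 001001 001001 001001
ind13 , 002002 001001 001002 002002 001001 001001 002002 002002 001002 001001 001001 001001
ind14 , 002002 001002 002002 002002 001001 001001 001002 002002 001002 001001 001001 001001
ind15 , 002002 001002 002002 002002 001001 001001 001002 002002 001002 001001 001001 001001
ind1.1 , 001001 001001 001001 001001 001001 001001 001001 001001 001001 001001 001001 001001
POP
ind16 , 002002 001002 002002 001001 001001 001001 002002 002002 001002 001002 002002 001001
ind17 , 002002 001001 002002 001001 001001 001001 002002 001002 001001 002002 001001 001001
ind18 , 002002 001002 002002 001001 001001 001001 002002 002002 001001 002002 001002 001001
ind19 , 002002 001002 002002 001001 001001 001001 002002 002002 001001 001002 001001 002002
ind20 , 002002 002002 002002 001001 001001 001001 002002 002002 001002 001001 001001 001002
ind21 , 002002 001002 002002 001001 001001 001001 002002 002002 001001 002002 001002 001001
ind22 , 002002 001002 002002 001001 001001 001001 002002 002002 001001 002002 001001 001001
ind23 , 002002 001002 002002 001001 001001 001001 002002 002002 001001 002002 001002 001001
ind24 , 002002 001002 002002 001001 001001 001001 002002 002002 001002 001001 001001 001002
ind25 , 002002 001002 002002 001001 001001 001001 002002 002002 001002 001002 001001 001001
ind26 , 002002 002002 002002 001001 001001 001001 002002 002002 001001 001002 001001 001001
ind27 , 002002 001001 002002 001001 001001 001001 002002 001002 002002 001001 001001 001001
ind28 , 002002 001002 002002 001001 001001 001001 002002 002002 001001 001002 001001 001001
ind29 , 002002 001001 002002 001001 001001 001001 002002 002002 001001 002002 001001 002002
ind30 , 002002 001002 002002 001001 001001 001001 002002 002002 001001 001002 001001 001001
ind2.1 , 002002 002002 002002 002002 002002 002002 002002 002002 002002 002002 002002 002002
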