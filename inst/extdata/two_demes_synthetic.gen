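synthetic two-deme microsatellite example (seeded generator output)
loc01
loc02
loc03
loc04
loc05
loc06
Pop
ind001 ,  0105 0205 0205 0102 0101 0105
ind002 ,  0305 0000 0202 0206 0000 0107
ind003 ,  0505 0000 0203 0106 0101 0101
ind004 ,  0305 0205 0303 0106 0101 0104
ind005 ,  0505 0202 0204 0000 0106 0104
ind006 ,  0505 0205 0203 0606 0106 0104
ind007 ,  0305 0202 0203 0106 0107 0104
ind008 ,  0505 0205 0202 0606 0106 0104
ind009 ,  0203 0000 0000 0506 0106 0107
ind010 ,  0000 0204 0203 0606 0101 0107
ind011 ,  0505 0205 0204 0606 0106 0107
ind012 ,  0505 0205 0203 0206 0102 0304
Pop
ind013 ,  0305 0000 0203 0106 0000 0909
ind014 ,  0305 0205 0205 0206 0606 0506
ind015 ,  0306 0505 0203 0106 0106 0909
ind016 ,  0000 0202 0205 0102 0707 0306
ind017 ,  0505 0405 0103 0106 0101 0909
ind018 ,  0105 0204 0205 0106 0106 0909
ind019 ,  0105 0000 0202 0206 0607 0509
ind020 ,  0505 0505 0202 0000 0106 0505
ind021 ,  0506 0305 0205 0202 0101 0509
ind022 ,  0105 0405 0305 0102 0107 0505
ind023 ,  0105 0405 0205 0606 0107 0406
ind024 ,  0506 0000 0202 0202 0101 0506
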