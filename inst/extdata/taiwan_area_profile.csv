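area_code,area_km2,n_providers,n_cases,n_general,n_high
Taipei City,271.8,162,1564,996,568
New Taipei City,2052.6,227,1554,1010,544
Keelung City,132.8,38,105,81,24
Taoyuan City,1221.0,102,622,409,213
Hsinchu County,1427.5,48,153,84,69
Hsinchu City,104.2,26,90,59,31
Miaoli County,1820.3,41,194,122,72
Taichung City,2214.9,149,868,563,305
Changhua County,1074.4,90,416,292,124
Nantou County,4106.4,42,232,178,54
Yunlin County,1290.8,72,388,251,137
Chiayi County,1903.6,54,358,261,97
Chiayi City,60.0,40,152,103,49
Tainan City,2191.7,169,965,719,246
Kaohsiung City,2951.9,237,1005,737,268
Pingtung County,2775.6,98,394,279,115
Yilan County,2143.6,72,263,197,66
Hualien County,4628.6,40,181,126,55
Taitung County,3515.3,47,123,78,45
Penghu County,126.9,13,32,20,12
Kinmen County,151.7,9,42,27,15
Lienchiang County,28.8,6,3,1,2
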