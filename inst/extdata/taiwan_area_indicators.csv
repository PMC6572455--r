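area_code,n_providers,pwd_all,tld_all,pwd_general,tld_general,pwd_high,tld_high
Taipei City,162,650,1200,350,1300,NA,600
New Taipei City,227,200,2200,200,1800,NA,950
Keelung City,38,300,1250,NA,NA,NA,550
Taoyuan City,102,200,3250,250,1850,150,2250
Hsinchu County,48,200,1500,300,1200,NA,NA
Hsinchu City,26,150,NA,NA,1200,NA,NA
Miaoli County,41,150,2950,150,1000,NA,NA
Taichung City,149,150,3000,150,3000,150,2150
Changhua County,90,150,4750,NA,NA,NA,NA
Nantou County,42,150,3650,NA,4050,NA,NA
Yunlin County,72,NA,6250,NA,NA,NA,NA
Chiayi County,54,300,1200,400,700,NA,NA
Chiayi City,40,250,NA,350,NA,350,NA
Tainan City,169,350,1200,300,1450,450,4500
Kaohsiung City,237,350,1600,300,1700,300,1600
Pingtung County,98,150,3600,150,2950,NA,NA
Yilan County,72,150,1200,NA,1100,NA,NA
Hualien County,40,600,1700,550,1650,NA,NA
Taitung County,47,NA,1300,NA,NA,NA,900
Penghu County,13,NA,NA,NA,NA,NA,NA
Kinmen County,9,NA,NA,NA,NA,NA,NA
Lienchiang County,6,NA,NA,NA,NA,NA,NA
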