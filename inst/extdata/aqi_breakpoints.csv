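pollutant,period,iaqi,conc
SO2,24h,0,0
SO2,24h,50,50
SO2,24h,100,150
SO2,24h,150,475
SO2,24h,200,800
SO2,24h,300,1600
SO2,24h,400,2100
SO2,24h,500,2620
NO2,24h,0,0
NO2,24h,50,40
NO2,24h,100,80
NO2,24h,150,180
NO2,24h,200,280
NO2,24h,300,565
NO2,24h,400,750
NO2,24h,500,940
PM10,24h,0,0
PM10,24h,50,50
PM10,24h,100,150
PM10,24h,150,250
PM10,24h,200,350
PM10,24h,300,420
PM10,24h,400,500
PM10,24h,500,600
PM25,24h,0,0
PM25,24h,50,35
PM25,24h,100,75
PM25,24h,150,115
PM25,24h,200,150
PM25,24h,300,250
PM25,24h,400,350
PM25,24h,500,500
CO,24h,0,0
CO,24h,50,2
CO,24h,100,4
CO,24h,150,14
CO,24h,200,24
CO,24h,300,36
CO,24h,400,48
CO,24h,500,60
O3,8h,0,0
O3,8h,50,100
O3,8h,100,160
O3,8h,150,215
O3,8h,200,265
O3,8h,300,800
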