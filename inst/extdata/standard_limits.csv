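pollutant,limit,statistic,unit
SO2,60,annual_mean,ug/m3
NO2,40,annual_mean,ug/m3
PM10,70,annual_mean,ug/m3
PM25,35,annual_mean,ug/m3
CO,4,daily_p95,mg/m3
O3,160,o3_8h_p90,ug/m3
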