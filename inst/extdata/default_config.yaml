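# Default pipeline configuration: fully synthetic one-year study.
synthetic: true
seed: 20220101
year: 2022
n_stations: 2

generator:
  noise_sd: 0.12
  heating_multiplier: 2.5
  baselines:            # daily-scale levels; ug/m3 except CO (mg/m3)
    SO2: 7
    NO2: 30
    PM10: 65
    PM25: 40
    CO: 0.9
    O3: 70
  amplitudes:           # seasonal amplitude on the log scale
    SO2: 0.0
    NO2: 0.35
    PM10: 0.40
    PM25: 0.50
    CO: 0.50
    O3: 0.60
  dust:                 # month -> number of injected dust events
    counts: {3: 1, 4: 6, 5: 6, 7: 1, 8: 1, 9: 2, 10: 4, 11: 1}
    pm10_range: [200, 700]
    ratio: 0.25
    duration_h: 3

aqi:
  o3_percentile: 0.90
  min_valid_hours: 20

trend:
  alpha: 0.05

gra:
  xi: 0.5
  # Annual driver series (reference first) generated from grey laws.
  years: [2016, 2017, 2018, 2019, 2020, 2021, 2022]
  reference: {name: GDP, a: -0.08, u: 2500, x1: 2700}
  comparisons:
    - {name: SO2_emissions, a: 0.12, u: 60, x1: 45}
    - {name: NOx_emissions, a: 0.05, u: 52, x1: 50}
    - {name: PM_emissions,  a: 0.09, u: 75, x1: 60}

gm11:
  years: [2015, 2016, 2017, 2018, 2019, 2020, 2021, 2022]
  horizon: 3
  noise_sd: 0.01
  series:               # generating grey parameters per indicator
    SO2:  {a: 0.119,  u: 15.45,  x1: 12}
    NO2:  {a: 0.068,  u: 53.46,  x1: 46}
    PM10: {a: 0.053,  u: 113.94, x1: 100}
    PM25: {a: 0.105,  u: 78.72,  x1: 62}
    CO:   {a: 0.115,  u: 4.05,   x1: 3.2}
    O3:   {a: -0.047, u: 98.60,  x1: 110}
  thresholds: {PM10: 70, PM25: 35, O3: 160}
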