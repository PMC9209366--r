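# Illustrative tunnel-commute scenario: aged filter, no ionization, Low
# fan airflow (~40 L/s), two occupants, synthetic traffic-like outdoor
# aerosol and tunnel CO2. The outdoor aerosol is generated from a
# lognormal mixture (synthetic), not measured data.
vehicle:
  file: vehicle_default.yaml
filter:
  status: aged_500h
  ionization: "off"
  eta_mode: average
ventilation:
  fan_level: low
  recirculation: 0.0
  vspeed_kmh: 0
occupants:
  "N": 2
  Vbr_lmin: 6.5
  Cbr_ppm: 40000
outdoor:
  co2_ppm: 716
  particles:
    model:
      total_count: 30000
      modes:
        - {fraction: 0.55, gmd_nm: 30, gsd: 1.8}
        - {fraction: 0.44, gmd_nm: 90, gsd: 2.0}
        - {fraction: 0.01, gmd_nm: 500, gsd: 2.2}
density: 1000
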