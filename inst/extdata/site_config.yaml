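# Measured site configuration: water column, sediment composition, budget
# and gas-exchange settings. Any key omitted falls back to these defaults.
water:
  ta: 2596          # umol kg-1
  dic: 2295         # umol kg-1
  salinity: 38
  temperature: 26   # degC
constants:
  set: lueker
sediment:
  f_ic: 97.5        # percent of sediment
  f_oc: 2.1
  f_crs: 0.3
  f_fe: 0.5
  interpretation: molar
budget:
  sar_min: 1.9      # g m-2 yr-1
  sar_max: 1042
  steps: 50
  water_mass: 1000  # kg m-2
  crs_split: [0.5, 0.5]
  mode: linearized
gasex:
  k: 11.7           # cm hr-1
  rho: 1000         # kg m-3
  flux_band: [610, 700]  # umol m-2 hr-1
scenarios:
  balancing_redox_scale: 1
  amendment:
    oc_scale: 10
    redox_scale: 45
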