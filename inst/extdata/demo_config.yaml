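# Demonstration run: a 45-year synthetic area record with the default climate
# and mortality settings, full 16-definition catalogue, 10,000-year Monte
# Carlo, and a warmed/aged future projection.
simulate: true
sim:
  n_years: 45
selection_group: all
mc:
  n_years: 10000
  seed: 7
return_periods: [50, 100]
future:
  enabled: true
  warming: 3.0
  spell_rate_factor: 2
  elder_share: 0.3153
  n_years: 10000
seed: 42
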