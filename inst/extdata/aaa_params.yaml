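prevalence_aaa:
  point: 0.03
  low: 0.01
  high: 0.04
  family: beta
proportion_small:
  point: 0.789
  low: 0.789
  high: 0.789
  family: dirichlet
proportion_medium:
  point: 0.12
  low: 0.12
  high: 0.12
  family: dirichlet
proportion_large:
  point: 0.091
  low: 0.091
  high: 0.091
  family: dirichlet
p_incidence:
  point: 0.00207
  low: 0.0013
  high: 0.0029
  family: gamma
p_small_to_medium:
  point: 0.037
  low: 0.033
  high: 0.042
  family: beta
p_medium_to_large:
  point: 0.175
  low: 0.119
  high: 0.231
  family: beta
p_rupture_small:
  point: 0.00023
  low: 0.00013
  high: 0.00038
  family: beta
p_rupture_medium:
  point: 0.0016
  low: 0.00043
  high: 0.00588
  family: beta
p_rupture_undetected_large:
  point: 0.0282
  low: 0.01974
  high: 0.03666
  family: beta
p_rupture_detected_large:
  point: 0.0125
  low: 0.008
  high: 0.018
  family: beta
p_rupture_contraindicated_large:
  point: 0.0282
  low: 0.01974
  high: 0.03666
  family: beta
p_opportunistic_detection:
  point: 0.0114
  low: 0.00798
  high: 0.01482
  family: beta
p_emergency_surgery_after_rupture:
  point: 0.368
  low: 0.2
  high: 0.5
  family: beta
p_elective_surgery_if_large:
  point: 0.918
  low: 0.85
  high: 0.95
  family: beta
p_reop_evar_annual:
  point: 0.063
  low: 0.0441
  high: 0.0819
  family: beta
p_reop_osr_annual:
  point: 0.039
  low: 0.0273
  high: 0.0507
  family: beta
attendance:
  point: 0.75
  low: 0.65
  high: 0.85
  family: beta
prop_evar_emergency:
  point: 0.05
  low: 0.0
  high: 0.1
  family: beta
prop_evar_elective:
  point: 0.8
  low: 0.7
  high: 0.9
  family: beta
p_death_elective_evar:
  point: 0.013
  low: 0.004
  high: 0.023
  family: beta
p_death_elective_osr:
  point: 0.03
  low: 0.021
  high: 0.05
  family: beta
p_death_emergency_evar:
  point: 0.307
  low: 0.152
  high: 0.492
  family: beta
p_death_emergency_osr:
  point: 0.5
  low: 0.35
  high: 0.65
  family: beta
utility_65_69:
  point: 0.83
  low: 0.83
  high: 0.83
  family: fixed
utility_70_74:
  point: 0.81
  low: 0.81
  high: 0.81
  family: fixed
utility_75_79:
  point: 0.79
  low: 0.79
  high: 0.79
  family: fixed
utility_80_plus:
  point: 0.74
  low: 0.74
  high: 0.74
  family: fixed
disutility_postop:
  point: -0.02
  low: -0.02
  high: -0.02
  family: fixed
discount_rate_annual:
  point: 0.03
  low: 0.0
  high: 0.06
  family: fixed
cost_evar:
  point: 12433.0
  low: 8289.0
  high: 20722.0
  family: gamma
cost_osr:
  point: 6442.0
  low: 4295.0
  high: 10737.0
  family: gamma
cost_screen:
  point: 39.17
  low: 25.25
  high: 57.29
  family: normal
cost_followup_small_per_cycle:
  point: 9.79
  low: 6.31
  high: 14.32
  family: normal
cost_followup_medium_per_cycle:
  point: 19.58
  low: 12.63
  high: 28.64
  family: normal
cycles_per_year: 4.0
start_age: 65.0
end_age: 100.0
dirichlet_concentration: 100.0
reop_window_years_evar: 2.0
reop_window_years_osr: 1.0
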