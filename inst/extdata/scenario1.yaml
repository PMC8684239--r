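# Scenario 1: accrual over [1, 270] days, constant event hazard 0.0025/day
lambda12: 0.0025
T1: 270
pop_size: 50000
n_sim: 5000
n_obs_levels: [30, 60, 90, 120, 250, 500]
pe_levels: [0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0]
seed: 1
B_ci: 1000
truth_source: population_fit
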