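# Demonstration run: small synthetic cohort, 2012 estimates with a 16-year
# reference lookback, plus annual trends for 2001-2012.
seed: 1
n_index: 300
control_pool_multiplier: 25
match_ratio: 5
estimation_year: 2012
data_start_year: 1996
data_end_year: 2012
burn_in_year: 1986
ref_k: 16
k_list: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16]
trend_years: [2001, 2004, 2008, 2012]
dropout_rate: 0.0
definitions: case_definitions.yaml
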