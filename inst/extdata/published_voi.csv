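subset,evppi_pp,pop_1y_million,pop_5y_million
all,709,194,971
all_costs,58,16,79
all_utilities,118,32,161
all_costs_and_utilities,403,110,552
all_abstinence_probabilities,473,130,648
all_depression_selfharm_probabilities,575,157,787
nrt_std_vs_varenicline_std_prob_cost_util,544,149,745
nrt_std_vs_varenicline_std_probabilities_only,528,145,723
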