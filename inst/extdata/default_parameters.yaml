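meta:
  seed: 1
  generator: quitcea-defaults
  standard_roster: yes
strata:
- stratum_id: male_18_34
  sex: male
  age_band: 18-34
  cohort_share: 0.19
  all_cause_mortality: 0.0009
  mean_age: 26
- stratum_id: male_35_64
  sex: male
  age_band: 35-64
  cohort_share: 0.27
  all_cause_mortality: 0.0042
  mean_age: 49
- stratum_id: male_65plus
  sex: male
  age_band: 65+
  cohort_share: 0.06
  all_cause_mortality: 0.036
  mean_age: 72
- stratum_id: female_18_34
  sex: female
  age_band: 18-34
  cohort_share: 0.16
  all_cause_mortality: 0.0004
  mean_age: 26
- stratum_id: female_35_64
  sex: female
  age_band: 35-64
  cohort_share: 0.26
  all_cause_mortality: 0.0028
  mean_age: 49
- stratum_id: female_65plus
  sex: female
  age_band: 65+
  cohort_share: 0.06
  all_cause_mortality: 0.03
  mean_age: 72
diseases:
  COPD:
    disease_id: COPD
    incidence:
      male_18_34: 0.0001
      male_35_64: 0.001
      male_65plus: 0.003
      female_18_34: 0.0001
      female_35_64: 0.001
      female_65plus: 0.003
    prevalence:
      male_18_34: 0.002
      male_35_64: 0.03
      male_65plus: 0.08
      female_18_34: 0.002
      female_35_64: 0.03
      female_65plus: 0.08
    excess_mortality:
      male_18_34: 0.01
      male_35_64: 0.035
      male_65plus: 0.06
      female_18_34: 0.01
      female_35_64: 0.035
      female_65plus: 0.06
    rr_smoker: 12.0
    rr_recent_quitter: 9.0
    rr_long_quitter: 4.0
    annual_cost: 2000.0
    utility_value: 0.71
  lung_cancer:
    disease_id: lung_cancer
    incidence:
      male_18_34: 2.0e-05
      male_35_64: 0.0004
      male_65plus: 0.001
      female_18_34: 2.0e-05
      female_35_64: 0.0004
      female_65plus: 0.001
    prevalence:
      male_18_34: 0.0001
      male_35_64: 0.002
      male_65plus: 0.005
      female_18_34: 0.0001
      female_35_64: 0.002
      female_65plus: 0.005
    excess_mortality:
      male_18_34: 0.3
      male_35_64: 0.35
      male_65plus: 0.4
      female_18_34: 0.3
      female_35_64: 0.35
      female_65plus: 0.4
    rr_smoker: 15.0
    rr_recent_quitter: 10.0
    rr_long_quitter: 5.0
    annual_cost: 9000.0
    utility_value: 0.61
  CHD:
    disease_id: CHD
    incidence:
      male_18_34: 0.0002
      male_35_64: 0.003
      male_65plus: 0.008
      female_18_34: 0.0002
      female_35_64: 0.003
      female_65plus: 0.008
    prevalence:
      male_18_34: 0.005
      male_35_64: 0.06
      male_65plus: 0.15
      female_18_34: 0.005
      female_35_64: 0.06
      female_65plus: 0.15
    excess_mortality:
      male_18_34: 0.02
      male_35_64: 0.045
      male_65plus: 0.08
      female_18_34: 0.02
      female_35_64: 0.045
      female_65plus: 0.08
    rr_smoker: 2.5
    rr_recent_quitter: 2.0
    rr_long_quitter: 1.3
    annual_cost: 1500.0
    utility_value: 0.76
  stroke:
    disease_id: stroke
    incidence:
      male_18_34: 0.0001
      male_35_64: 0.0015
      male_65plus: 0.006
      female_18_34: 0.0001
      female_35_64: 0.0015
      female_65plus: 0.006
    prevalence:
      male_18_34: 0.002
      male_35_64: 0.025
      male_65plus: 0.08
      female_18_34: 0.002
      female_35_64: 0.025
      female_65plus: 0.08
    excess_mortality:
      male_18_34: 0.04
      male_35_64: 0.07
      male_65plus: 0.11
      female_18_34: 0.04
      female_35_64: 0.07
      female_65plus: 0.11
    rr_smoker: 2.0
    rr_recent_quitter: 1.7
    rr_long_quitter: 1.2
    annual_cost: 3000.0
    utility_value: 0.63
  asthma:
    disease_id: asthma
    incidence:
      male_18_34: 0.002
      male_35_64: 0.001
      male_65plus: 0.0005
      female_18_34: 0.002
      female_35_64: 0.001
      female_65plus: 0.0005
    prevalence:
      male_18_34: 0.08
      male_35_64: 0.07
      male_65plus: 0.06
      female_18_34: 0.08
      female_35_64: 0.07
      female_65plus: 0.06
    excess_mortality:
      male_18_34: 0.0003
      male_35_64: 0.0008
      male_65plus: 0.002
      female_18_34: 0.0003
      female_35_64: 0.0008
      female_65plus: 0.002
    rr_smoker: 1.6
    rr_recent_quitter: 1.4
    rr_long_quitter: 1.2
    annual_cost: 700.0
    utility_value: 0.86
baseline_risks:
  p_abstain_nrt_std: 0.212
  p_depression_nrt_std: 0.077501662623292
  p_selfharm_nrt_std: 0.005058121563522
relapse:
  p_relapse_short: 0.13
  p_relapse_long: 0.03
  p_relapse_10plus: 0.0009
adverse_events:
  disutility_depression: 0.2
  cost_depression: 900.0
  disutility_selfharm: 0.15
  cost_selfharm: 2500.0
  fatal_fraction_selfharm: 0.05
economics:
  discount_rate: 0.035
  wtp: 20000.0
  population_per_year: 274021
  cohort_size: 10000
  psa_draws: 5000
  horizon: 100
  baseline_utility:
    male_18_34: 0.93
    male_35_64: 0.85
    male_65plus: 0.78
    female_18_34: 0.92
    female_35_64: 0.83
    female_65plus: 0.76
interventions:
- intervention_id: nrt_low
  licensed: yes
  course_cost: 100.0
- intervention_id: nrt_std
  licensed: yes
  course_cost: 160.0
- intervention_id: nrt_high
  licensed: yes
  course_cost: 220.0
- intervention_id: bupropion_low
  licensed: yes
  course_cost: 70.0
- intervention_id: bupropion_std
  licensed: yes
  course_cost: 85.0
- intervention_id: varenicline_low
  licensed: yes
  course_cost: 140.0
- intervention_id: varenicline_std
  licensed: yes
  course_cost: 163.0
- intervention_id: ecig_low
  licensed: no
  course_cost: 83.0
- intervention_id: ecig_high
  licensed: no
  course_cost: 110.0
- intervention_id: bupropion_std_nrt_high
  licensed: no
  course_cost: 305.0
- intervention_id: varenicline_low_nrt_std
  licensed: no
  course_cost: 300.0
- intervention_id: varenicline_std_nrt_std
  licensed: no
  course_cost: 323.0
- intervention_id: varenicline_std_nrt_high
  licensed: no
  course_cost: 383.0
- intervention_id: varenicline_std_bupropion_std
  licensed: no
  course_cost: 248.0
relative_effects:
  log_or_abstinence:
    nrt_low: -0.272715448554515
    nrt_std: 0.0
    nrt_high: 0.214299526517757
    bupropion_low: -0.073382545934024
    bupropion_std: 0.104600609261333
    varenicline_low: 0.214299526517757
    varenicline_std: 0.465613954798663
    ecig_low: 0.559140012809487
    ecig_high: 0.465613954798663
    bupropion_std_nrt_high: 0.368450206345015
    varenicline_low_nrt_std: 1.071749758368979
    varenicline_std_nrt_std: 1.071749758368979
    varenicline_std_nrt_high: 0.604726757261381
    varenicline_std_bupropion_std: 0.693872606779643
  log_or_mane:
    nrt_low: .na.real
    nrt_std: 0.0
    nrt_high: 0.034439148909234
    bupropion_low: .na.real
    bupropion_std: 0.279561606942219
    varenicline_low: -0.109903159819504
    varenicline_std: 0.163151255097807
    ecig_low: .na.real
    ecig_high: .na.real
    bupropion_std_nrt_high: 0.333922816161107
    varenicline_low_nrt_std: .na.real
    varenicline_std_nrt_std: 0.222728132179054
    varenicline_std_nrt_high: 0.279561606942219
    varenicline_std_bupropion_std: 0.386045087344669
harm_map:
  nrt_low: nrt_std
  ecig_low: nrt_std
  ecig_high: nrt_high
  bupropion_low: bupropion_std
  varenicline_low_nrt_std: varenicline_std_nrt_std
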