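# quitcea

Cost-effectiveness and value-of-information analysis of smoking-cessation
interventions, as a self-contained R package.

## The problem

Fourteen interventions are compared for a cohort of UK adult smokers
making one quit attempt: nicotine replacement therapy (NRT) at low,
standard and high dose, bupropion (low/standard), varenicline
(low/standard), e-cigarettes (low/high nicotine), and five combination
therapies. Seven are UK-licensed and form the base case. The analysis
weighs each intervention's one-year sustained-abstinence benefit against
its cost and its neuropsychiatric harms — one-year probabilities of
attributable depression and self-harm, with costs, QALY decrements and a
fatal fraction of self-harm.

The engine is a deterministic Markov cohort model with annual cycles on
the state space

```
stratum (sex x age band)  x  smoking status (smoker | quit 1..10y | quit 11+y)
                          x  disease (none | COPD | lung cancer | CHD | stroke | asthma)
```

with *dead* absorbing and a lifetime horizon (maximum age 100). After the
quit attempt at cycle 1, quitters relapse at 0.13/yr (years 1–5),
0.03/yr (years 5–10) and 0.0009/yr thereafter; disease incidence and
excess mortality scale with smoking status through risk ratios. Costs and
QALYs are discounted at 3.5%/yr. Per-person lifetime outcomes feed a
standard decision-analytic layer: incremental analysis with simple and
extended dominance, net monetary benefit at £20,000/QALY,
cost-effectiveness acceptability curves (CEACs), rank-o-grams, and
expected value of perfect and partial perfect information (EVPI/EVPPI)
estimated by spline regression metamodelling on the PSA draws.

Parameters come from `generate_default_parameters()`, which anchors the
values printed in the main text of the published UK smoking-cessation
cost-effectiveness analysis (abstinence 0.212 on standard NRT; depression
and self-harm baselines 8,274/106,759 and 540/106,759; relapse rates;
discounting; the 274,021 annual quit attempts used for population
scaling) and fills the remainder — supplementary-table inputs with no
machine-readable source — with clearly labelled synthetic UK-plausible
values. The published probabilistic means and value-of-information
summaries ship as plain-text data (`published_cea_means()`,
`published_voi()`). See the vignette (`vignettes/model-methods.Rmd`) for
the full methods.

## Worked example

A base-case probabilistic run over the seven licensed interventions
(shortened here to 200 draws; the default is 5,000):

```r
library(quitcea)
res <- run_pipeline(run_config(scenario = "base", seed = 7, psa_draws = 200))
format_cea_table(res$cea_table)
```

```
     intervention total_cost total_qalys                 icer  enb     enb_95ci
1         nrt_low       3670      11.845                         0       (0, 0)
2   bupropion_low       3673      11.863                 £136  361   (198, 513)
3   bupropion_std       3700      11.900                 £738 1070  (903, 1215)
4 varenicline_low       3728      11.922 Extendedly dominated 1496 (1296, 1718)
5         nrt_std       3743      11.887            Dominated  777   (657, 896)
6 varenicline_std       3785      11.972               £1,178 2435 (2279, 2593)
7        nrt_high       3817      11.918            Dominated 1330 (1172, 1503)
  median_rank rank_iqr
1           6    (5-7)
2           6    (4-7)
3           4    (3-5)
4           3    (2-5)
5           4    (3-5)
6           1    (1-2)
7           3    (2-5)
```

Costs and QALYs are per cohort member, lifetime, discounted; ICERs run
along the efficiency frontier; `enb` is incremental net benefit at
£20,000/QALY against the least-cost option, with a bootstrap 95%
interval; ranks summarize the rank-o-gram. The same result object carries
the CEAC grid (`res$ceac`), the rank-probability matrix
(`res$rankogram`), and the value-of-information table:

```r
res$voi_table
```

```
                                         subset   evppi_pp pop_1y_million
1                                           all 397.504957    108.9247057
2                                     all_costs  13.282887      3.6397899
3                                 all_utilities   0.000000      0.0000000
4                       all_costs_and_utilities   1.580691      0.4331424
5                  all_abstinence_probabilities  17.980739      4.9271001
6         all_depression_selfharm_probabilities  13.358451      3.6604960
7     nrt_std_vs_varenicline_std_prob_cost_util   0.000000      0.0000000
8 nrt_std_vs_varenicline_std_probabilities_only  22.951482      6.2891880
  pop_5y_million
1     544.623529
2      18.198950
3       0.000000
4       2.165712
5      24.635500
6      18.302480
7       0.000000
8      31.445940
```

(`all` is the EVPI; population values use 274,021 annual quit attempts
over a 1- or 5-year horizon, in GBP million.)

`write_reports(res, "reports")` writes the tables, curves and a
reproducibility manifest as CSV/JSON. `run_config(scenario = "all")`
analyses all fourteen interventions; `scenario = "no_adverse_events"`
switches the neuropsychiatric harms off. The published mean outcomes can
be pushed through the same dominance machinery directly:

```r
efficiency_frontier(published_cea_means())
# frontier: nrt_low and ecig_low; the remaining 12 dominated or
# extendedly dominated; ICER of ecig_low vs nrt_low ~ £56/QALY
```

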