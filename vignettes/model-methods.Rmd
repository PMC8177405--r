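---
title: "A Markov cohort model of smoking-cessation interventions: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of smoking-cessation interventions: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quitcea)
```

## The decision problem

`quitcea` compares fourteen smoking-cessation interventions offered to a
cohort of UK adult smokers making one quit attempt: nicotine replacement
therapy (NRT) at low, standard and high dose, bupropion at low and standard
dose, varenicline at low and standard dose, e-cigarettes at low and high
nicotine strength, and five combination therapies. Seven of the fourteen
(the NRT, bupropion and varenicline single-agent options) are UK-licensed;
the base-case analysis is restricted to those, and a secondary analysis
covers all fourteen. Outcomes are lifetime discounted costs (GBP, 2019
prices) and quality-adjusted life years (QALYs) per cohort member,
compared by incremental cost-effectiveness ratios (ICERs), net monetary
benefit at £20,000/QALY, cost-effectiveness acceptability curves,
rank-o-grams, and expected value of (partial) perfect information.

A distinctive feature of the analysis is that it charges the interventions
for their neuropsychiatric harms: one-year probabilities of
intervention-attributable depression and self-harm, with one-off costs,
QALY decrements, and a fatal fraction of self-harm events. A
`no_adverse_events` scenario removes these to show their influence.

## Model structure

The engine (`run_cohort()`, `transition()`) is a deterministic
expected-value Markov cohort model — no microsimulation — on the state
space

> stratum (sex × age band at entry) × smoking status × disease state,

with *dead* absorbing. The cohort (10,000 smokers by default) enters
distributed over six strata (male/female × ages 18–34, 35–64, 65+), each
stratum carrying its own all-cause mortality, baseline utility and disease
epidemiology. Disease states are mutually exclusive first-event states:
none, COPD, lung cancer, coronary heart disease, stroke, asthma. Smoking
status is a smoker bin plus a years-since-quit counter (1–10, then 11+),
tracked because both relapse and disease risk depend on time since
quitting. Cycles are annual with no half-cycle correction; members age one
year per cycle, adopt the next age band's rates when they cross a band
boundary, and leave the model after the cycle in which they reach the
maximum age (100).

**Cycle 1 — the quit attempt.** A fraction `p_abstain` of smokers becomes
quitters with counter 1. The whole treated cohort is charged the one-off
course cost, and the depression/self-harm probabilities generate one-off
costs and QALY decrements; the fatal fraction of self-harm events moves
members to dead. All cycle-1 amounts are discounted one period.

**Subsequent cycles** apply, in order:

1. *Relapse*: quitters revert to smoking with annual probability 0.13
   (years 1–5 since quitting), 0.03 (years 5–10) or 0.0009 (10+ years).
   Relapsed members never re-quit within the model.
2. *Disease incidence*: disease-free members acquire each disease with the
   never-smoker incidence of their current age band multiplied by the risk
   ratio of their smoking status (smoker, recent quitter < 5 years,
   long-term quitter ≥ 5 years), clamped so no probability exceeds one.
3. *Mortality*: all-cause mortality plus, for diseased members, a disease
   excess scaled by the same status risk ratios.
4. *Advance*: counters and ages increment.

Costs (annual disease costs) and QALYs (baseline utility for disease-free
members, disease utility weights otherwise) accrue each cycle and are
discounted at 3.5% per year.

Because the post-attempt dynamics do not depend on which intervention was
used, every intervention's trajectory is a mixture of two cohort runs (a
member smoking at cycle 1, and one who just quit). `run_psa()` exploits
this: two engine runs per draw instead of fourteen, bit-identical (to
~1e-13) with the direct per-intervention computation — this is verified in
the test suite.

## Parameters and the synthetic generator

`generate_default_parameters()` builds the complete input set. Values
printed in the main text of the published UK cost-effectiveness analysis
this package re-implements are anchored exactly:

| Quantity | Value |
|---|---|
| One-year sustained abstinence on standard-dose NRT | 0.212 |
| One-year depression baseline (counts) | 8,274 / 106,759 |
| One-year self-harm baseline (counts) | 540 / 106,759 (0.5%) |
| Annual relapse (years 1–5, 5–10, 10+) | 0.13, 0.03, 0.0009 |
| Discount rate (costs and QALYs) | 3.5% |
| Willingness to pay | £20,000/QALY |
| Annual quit attempts (population scaling) | 274,021 |
| Cohort size | 10,000 |

The remaining inputs (disease epidemiology, costs, utilities, course
costs, the full relative-effect posteriors) are published only in
supplementary tables that are not available in machine-readable form, so
the generator carries clearly labelled SYNTHETIC values: UK-plausible
magnitudes chosen once and fixed (see `R/defaults.R`). They are inputs of
convenience, not published data, and headline cost/QALY totals computed
from them are therefore *structurally* comparable with the published
tables (same rosters, same dominance machinery) but not numerically equal
to them. The published probabilistic means and value-of-information
figures themselves ship as plain-text data (`published_cea_means()`,
`published_voi()`) so the dominance and population-scaling machinery can
be exercised against the printed numbers.

### Relative effects

Treatment effects enter as log odds ratios versus NRT standard (the
baseline-risk reference) for two outcomes: one-year sustained abstinence
and major adverse neuropsychiatric events (MANE). A single MANE log OR per
intervention drives both depression and self-harm, applied separately to
each baseline. Mapping is on the log-odds scale,

\[ p = \operatorname{logit}^{-1}(\operatorname{logit}(p_0) + \log OR), \]

the standard scale for binary-outcome network meta-analysis: it keeps
every mapped probability inside (0, 1), is exactly invertible, and is
strictly increasing in the log OR. A risk-ratio alternative
(`scale = "rr"`) exists for sensitivity analysis.

Interventions without direct neuropsychiatric evidence borrow a donor
column through a harm-assumption map (`default_harm_map()`): NRT low and
e-cigarette low borrow NRT standard, e-cigarette high borrows NRT high,
bupropion low borrows bupropion standard, and varenicline low + NRT
standard borrows varenicline standard + NRT standard — same active
ingredient, or no dose-response evidence. Borrowing shares the donor's
*draws*, hence its correlations.

In place of a real Bayesian network-meta-analysis posterior,
`generate_nma_draws()` emulates one: correlated multivariate normal draws
on the log-OR scale (exchangeable correlation 0.3 by default), calibrated
per intervention so the induced mean of the mapped probability equals the
anchor mean exactly (solved by quadrature and root-finding) and the
interval width matches on the logit scale. The three abstinence anchors
printed in the main text (0.44 (0.17–0.74), 0.44 (0.23–0.67), 0.32
(0.12–0.63)) are reproduced; the others are synthetic.

### Probabilistic sensitivity analysis

`sample_psa()` draws complete parameter-set realizations:
probabilities and utilities from Beta distributions (count-derived
effective sample sizes where counts are published: 106,759 for the
depression and self-harm baselines; interval-fitted Betas for the relapse
probabilities), costs from moment-matched Gamma distributions, and
per-stratum epidemiology vectors scaled by common lognormal multipliers so
the age/sex gradient is preserved within a draw. Every sampled set passes
the same validator as the deterministic set. The draw matrix
(`param_matrix`) doubles as the covariate matrix for the EVPPI metamodel.

## Decision analysis

`efficiency_frontier()` performs standard incremental analysis: simple
dominance, then iterative removal of extendedly dominated options until
sequential ICERs strictly increase. The test suite checks it against a
brute-force oracle that searches over explicit two-option mixtures.
`ceac()` splits exact ties equally (curves sum to one), and `rankogram()`
assigns tied groups equal mass over the rank positions they span, making
the rank-probability matrix doubly stochastic.

Incremental net benefit is reported against NRT low (the least-cost
option, matching the reporting convention of the published tables) with a
95% bootstrap percentile interval of the mean; the interval is a seeded
Monte-Carlo quantity, reproducible under the pipeline seed.

## Value of information

Per-person EVPI is `mean(max_i NB) − max_i mean(NB)` over the draws.
EVPPI for a parameter subset uses a regression metamodel: each
intervention's net benefit is regressed on the subset with cubic
regression spline smooths (`mgcv::gam`); subsets larger than four
parameters are first projected onto their leading principal components, a
low-rank approximation in the spirit of Gaussian-process metamodelling.
Basis dimensions shrink automatically when draws are scarce so the
metamodel stays identifiable. Estimates are capped into `[0, EVPI]` (the
theoretical bounds, which regression noise can violate). The test suite
compares the estimator with enumeration, closed-form bivariate-normal
results and known-conditional-mean oracles on 1–2 parameter toys.

Population values multiply the per-person value by 274,021 annual quit
attempts and a 1- or 5-year decision horizon, undiscounted, reported in
GBP million. The subset rosters reported by `voi_report()` mirror the
published table: all parameters, costs, utilities, costs + utilities,
abstinence probabilities, depression/self-harm probabilities, and two
head-to-head subsets restricted to NRT standard versus varenicline
standard.

## Numerical and design choices

- *Expected-value arithmetic.* The engine propagates expected occupancy,
  so results are deterministic given parameters; Monte Carlo error enters
  only through the PSA draws. Mass conservation (alive + dead = cohort)
  holds to ~1e-12 per cycle and is asserted in tests.
- *One-off adverse events.* Depression and self-harm are charged once at
  cycle 1 (probability × cost, probability × QALY decrement) rather than
  as chronic states — their published role is a one-year treatment-harm
  window, and only the fatal fraction of self-harm changes the state
  trajectory.
- *Immediate relapse reclassification.* A relapsed quitter is a smoker
  for every purpose (risk ratios, no re-quit) from the cycle of relapse.
- *Clamping.* Risk-ratio-scaled probabilities are clamped at one and the
  total acquisition probability renormalized if needed; clamp events are
  counted on the trace (`n_clamped`) rather than silently ignored.
- *Problem sizes.* 5,000 PSA draws, cohort 10,000, maximum age 100 and a
  £0–50,000 CEAC grid are package defaults chosen to match the published
  report layout and to keep the base case under a few minutes of CPU;
  all are configurable through `run_config()` and the parameter file.

## Reproducing an analysis

```{r, eval = FALSE}
library(quitcea)

# base case: licensed interventions, 5,000 draws, seed-reproducible
res <- run_pipeline(run_config(scenario = "base", seed = 1))
res$cea_table     # costs, QALYs, dominance, ICERs, net benefit, ranks
res$voi_table     # EVPI and EVPPI by parameter subset
write_reports(res, "reports")

# all fourteen interventions, and the published-means frontier
res14 <- run_pipeline(run_config(scenario = "all", seed = 1))
efficiency_frontier(published_cea_means())
```

Everything random — PSA sampling, synthetic posterior draws, bootstrap
intervals — derives from the single `seed`, and a repeated run is
byte-identical.
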