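# incrisk

Does a one-time self-report survey add predictive value on top of a
monthly-updating administrative risk score?  `incrisk` implements the
full evaluation pipeline for that question in the setting where it is
hardest: rare first-occurrence outcomes (violence perpetration and
victimization among new soldiers) observed over a few years of
follow-up, in a weighted cluster sample.

The package is aimed at biostatisticians and epidemiologists who work
with discrete-time survival data and composite ("predicted log-odds")
risk scores, and at anyone who needs a tested, reproducible reference
implementation of the concentration-of-risk evaluation used in the Army
STARRS risk-targeting literature.  Because the underlying military
records are restricted, the package ships a calibrated synthetic-cohort
simulator so that every stage of the pipeline is exercisable and
testable end to end.

## The model

Follow-up is discretized into person-months: subject *i* contributes one
row for every month *t* from the survey month (*t* = 0) until first
occurrence, service termination, or the administrative cutoff.  The
hazard is logistic,

    logit P(Y_it = 1 | at risk) = alpha_t + f(A_it, S_i)

where `alpha_t` is a per-month baseline (one dummy per month), `A_it`
is the standardized monthly administrative composite score, and `S_i`
is the standardized static survey composite score.  Candidate models
M1–M11 add, in a fixed ladder: the A main effect, its square, its
interaction with binned time (0–12 / 13–24 / 25+ months), then the
survey score S and its square, time interaction, and product with A.
Estimation maximizes the survey-weighted Bernoulli likelihood;
inference is design-based: cluster-sandwich (Taylor linearization)
covariance over sampling clusters and Wald chi-square tests of added
blocks select the best model at alpha = 0.05.

Model performance is summarized the way practitioners deploy such
scores: subjects are ranked by predicted 36-month cumulative risk and
cut into 20 weighted ventiles (5% each); the package reports the
concentration of risk (share of all observed cases) in the top
ventiles, the observed positive predictive value (events per 1000
person-months), the actuarially projected PPV at 36 months (cases per
1000 soldiers, with half-interval censoring adjustment), and the
proportional improvement of the combined model over the
administrative-only model.

## Worked example

```r
library(incrisk)

cfg    <- outcome_preset("victimization", seed = 1)   # n = 2,952 women
bundle <- run_pipeline(run_config(preset = "victimization", seed = 1))
bundle
#> Pipeline report bundle
#>   configure: preset victimization, n=2952, seed=1, alpha=0.05, ranking=cumulative
#>   simulate: 2952 subjects, 133 events
#>   expand: 70530 person-month rows
#>   correlate: median within-month r = 0.239, trend r = -0.903
#>   ladder: base M2, selected M6
#>   evaluate: morbid risk 71.6/1000 at 36 months; best top-ventile concentration 14.8%
```

Reading the output: the simulated cohort of 2,952 women yields 133
reported victimization events in ~70k person-months at risk (the
configured incidence is 19.5 per 1000 person-years; at this cohort size
the monthly correlation estimates are noisy, hence the median of 0.239
against a configured 0.26).  The within-month correlation between the
administrative and survey scores declines with time in service (trend
r = −0.90).  The model ladder keeps the administrative score linear
(base M2) and finds that adding the survey score improves fit with no
time interaction (final model M6).  The actuarial life table projects a
36-month morbid risk of 71.6 per 1000 (weighted, hence seed-to-seed
variable at n = 2,952), and the 5% of women with the highest predicted
risk under the best model account for 14.8% of all observed cases —
three times the 5% expected by chance.  `bundle$improvements` holds the
proportional improvements of the best model over the
administrative-only model, and `write_tables(bundle, dir)` exports all
report tables with a checksummed manifest.

Individual stages are exported too: `simulate_study()`,
`expand_person_months()`, `standardize_scores()`,
`fit_hazard_model()`, `sandwich_covariance()`, `wald_test()`,
`run_model_ladder()`, `life_table()`, `ventile_report()`,
`within_month_correlations()`.

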