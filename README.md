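# faindex

Scoring, classification and predictive-validity analysis for a self-report
**Functional Ability (FA) index** that screens community-dwelling senior
citizens for early functional decline.

## The index

Eleven questionnaire items yield six **frailty-risk** indicators and six
**robustness-resource** indicators:

| Risks (1 point each) | Resources (1 point each) |
|---|---|
| unintentional weight loss ≥ 5 kg / 6 months | walks 500 m without difficulty or help |
| changed the way of walking 1 km | walks outside ≥ 3 days/week |
| changed the way of climbing 10 steps | any moderate activity in the past week |
| changed the way of getting in/out of a car or bus | any strenuous activity in the past week |
| walks outside ≤ 2 days/week | paid or volunteer work in the past week |
| any fall in the past 12 months | no activity limitation from fear of falling |

One question — outside-walking frequency — carries double weight: a low
frequency counts as a risk, a high frequency as a resource, so exactly one
of the two indicators fires and the risk score *R* ∈ {0..6} and resource
score *S* ∈ {0..6} satisfy *R* + *S* ≤ 11.

Classification is the 2×2 grid on (*R* ≤ 2 vs ≥ 3) × (*S* ≥ 3 vs ≤ 2):

|  | S = 3–6 | S = 0–2 |
|---|---|---|
| **R = 0–2** | Robust | preFrail |
| **R = 3–6** | postRobust | Frail |

For transition analyses postRobust and preFrail are pooled into a single
**Transient** class. Records with any missing answer are flagged
unscorable and excluded from denominators (complete-case rule); nothing is
imputed.

The package provides, as separate composable layers:

- **Scoring** (`fa_indicators`, `fa_classify`, `fa_score_cohort`) with a
  fixed data dictionary (`fa_questions`) and CSV import/export.
- **A calibrated synthetic-cohort generator** (`fa_sim_config`,
  `fa_generate_cohort`): all items are driven by one latent frailty trait
  through logistic item models, so class membership is *emergent* from
  scored questionnaires; the item model is calibrated by quadrature (no
  simulation) so the scored class mixture hits a target (default
  60.9/13.1/10.2/15.8%). Conditional on class it draws age, sex and
  covariates, exponential death and nursing-care times over a 93-month
  horizon, wave-2 outcome categories and class-consistent wave-2
  questionnaires.
- **Survival machinery** (`fa_km`, `fa_lifetable`, `fa_logrank`,
  `fa_coxph`): product-limit and actuarial estimates, the k-sample
  log-rank test, and proportional-hazards regression reporting the
  likelihood-ratio test of the class factor after covariate adjustment.
- **Descriptive statistics** (`fa_spearman`, `fa_fisher`, `fa_welch`,
  `fa_transition_summary`, `fa_class_profile`): rank correlations with
  mid-ranks, exact tests, Welch t-tests, per-class "cases/n (%)" tables
  and the wave-1 → wave-2 transition summary with half-away-from-zero
  rounding to one decimal.
- **A pipeline** (`fa_simulate`, `fa_analyze`, `fa_report`,
  `fa_selftest`) plus a thin command-line front end
  (`inst/cli/fa_pipeline.R`, subcommands `simulate` / `score` / `analyze`
  / `report` / `selftest`).

## Worked example

```r
library(faindex)

fa_score_cohort(fa_example_records())[,
  c("id", "risk_score", "resource_score", "fa_class", "pooled_class")]
#>           id risk_score resource_score   fa_class pooled_class
#> 1     robust          0              6     Robust       Robust
#> 2 postrobust          3              5 postRobust    Transient
#> 3   prefrail          1              0   preFrail    Transient
#> 4      frail          6              0      Frail        Frail

cohort <- fa_generate_cohort(fa_sim_config(n = 1679, seed = 1))
fa_class_table(cohort$fa_class)
#>        class    n percent
#> 1     Robust 1023    60.9
#> 2 postRobust  233    13.9
#> 3   preFrail  164     9.8
#> 4      Frail  259    15.4

an <- fa_analyze(cohort)
an$logrank_death
#> Log-rank test: chi-square = 97.48, 3 df, p = 5.399e-21
#>            observed expected
#> Robust          100   176.05
#> postRobust       57    36.95
#> preFrail         38    24.74
#> Frail            82    39.25
an$coxph_death
#> Proportional-hazards fit (efron ties): n = 1651, events = 277
#> ...
#> Class likelihood ratio = 52, 3 df, p = 3e-11
```

The scored class shares of the simulated cohort track the configured
mixture up to binomial noise at n = 1679. The log-rank test and the
class-adjusted proportional-hazards fit recover the built-in mortality
gradient: the initially Frail die at roughly 3.4 times the hazard of the
initially Robust, and the class factor stays highly significant after
adjustment for age, sex and self-reported health. `an$transitions` gives
the wave-1 → wave-2 transition counts and row percentages;
`fa_report(an)` renders the whole bundle as a text report with every
percentage traceable to its numerator/denominator pair.

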