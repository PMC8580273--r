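# lcrope

Bayesian comparison of the three classic models of life-course
epidemiology — **accumulation** (all measurement occasions matter
equally), **critical period** (one occasion carries the whole effect)
and **sensitive periods** (anything in between) — with a principled
decomposition of the sensitive model into the most informative
credible ordering of occasions.

`lcrope` is for epidemiologists and biostatisticians analysing
repeated exposure measurements (e.g. body weight at five life stages)
against a later health outcome, and for methodologists studying the
operating characteristics of ROPE-based model comparison.

## The method in brief

The outcome is regressed on the exposure history through the
reparameterization `theta = delta * w`:

    y_i = alpha + delta * sum_j x_ij w_j + c_i' gamma + e_i,   e_i ~ N(0, sigma)

where `delta` is the scalar *lifetime effect* and `w` lies on the
`T`-part simplex, capturing each occasion's relative importance
(priors: Dirichlet(1) on `w`, Cauchy(0, 2.5) on `delta`,
lognormal(1, 1) on `sigma`; MCMC via JAGS).  Three summaries follow:

1. **Delta gate** — is the 95% credible interval for `delta` away from
   zero?  If not, there is no lifetime effect to decompose.
2. **ROPE test** — the range statistic `phi = max(w) - min(w)` equals
   0 under accumulation and 1 under a critical period.  Thresholds
   `a = 0.15`, `b = 0.85` cut `[0, 1]` into three regions of practical
   equivalence; each model's posterior probability is the fraction of
   posterior draws of `phi` in its region, and a model exceeding
   probability 0.9 is the conclusive decision.
3. **Finest credible rank (FCR)** — when the sensitive model wins, the
   occasions are ordered.  Starting from the most probable full
   ranking (e.g. `3|1|2`: occasion 3 least important, 2 most), the
   algorithm greedily merges adjacent blocks (`3|1|2 -> 1,3|2`),
   producing a nested chain with non-decreasing posterior probability,
   and reports the finest ranking reaching 90% credibility.

A simulation harness (`run_study()`) generates correlated-exposure
cohorts under each model family and scores the full pipeline:
confusion matrix, ranking-information recovery `q = r/r*`, and a
consistency audit of the FCR against the generating truth.

## A worked example

```r
library(lcrope)

sim <- simulate_lifecourse("nonlinear_sensitive", periods = 3, n = 3000,
                           delta_star = 2, seed = 17)
an <- analyze_lifecourse(sim$data, mcmc = mcmc_config(seed = 17))
print(an)
```

```
Life-course model comparison
============================

Posterior mean weights: (0.732, 0.227, 0.041)
Lifetime effect delta: 2.01 (1.97, 2.06) [95% CI]

ROPE test of life-course models (a = 0.15, b = 0.85)
  p(accumulation | y) = 0.0000
  p(sensitive    | y) = 1.0000
  p(critical     | y) = 0.0000
  decision (threshold 0.90): sensitive

Finest credible rank at beta = 0.90

Ranking                  Probability
3|2|1                    1.000  <- FCR
3|1,2                    1.000
1,2,3                    1.000

Conclusive: the FCR makes at least one distinction.
```

Reading it: the data were generated with true weights
`(0.75, 0.2, 0.05)` and lifetime effect 2.  The fit recovers the
weights, the delta gate passes (interval `(1.97, 2.06)` excludes 0),
the sensitive model takes essentially all posterior mass, and the FCR
resolves the *full* ordering `3|2|1` — occasion 1 most important —
with probability 1.000 at this sample size, matching the truth.

A command-line front end wrapping the same functions lives at
`inst/cli/lcrope.R`:

```sh
Rscript inst/cli/lcrope.R simulate --family nonlinear --T 3 --n 3000 --delta 2 --seed 17 --out cohort
Rscript inst/cli/lcrope.R analyze --data cohort.csv --out report
Rscript inst/cli/lcrope.R study --quick --seed 1 --out studydir
```

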