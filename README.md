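# daypref

Day-level dynamics of risk, ambiguity and time preferences from
ecological momentary assessment (EMA) data.

Intensive longitudinal designs now deliver economic choice tasks to
subjects' phones every day for weeks. `daypref` is an R package for
analysing such studies end-to-end, built around a two-group design
(patients with opioid use disorder vs. healthy controls, 28 days, up to
three task prompts per day). It provides:

* **Task design** — generators for the exact trial sets of a 54-trial
  monetary lottery task (known risk and ambiguity, gain and loss domains)
  and a 45-trial intertemporal choice task, plus the daily
  bonus-realization scheme (one random trial realized, capped at $6.60).
* **Choice models** — power utility with a linear ambiguity penalty,
  `EU = [p − β·A/2]·v^α`, linear-utility hyperbolic discounting,
  `U = v/(1 + κd)`, and logistic (softmax) choice,
  `Pr = 1/(1 + e^{−γΔU})`.
* **Estimation** — per-subject-per-day bounded maximum likelihood for
  (α, β, γ) and (κ, γ), with a brute-force grid oracle for verification
  and a summed-BIC comparison of the two delay codings of the sooner
  reward (0 vs. 7 days).
* **Variance decomposition** — intraclass correlations from
  random-intercept mixed models (REML, lme4), week-mean and
  random-day down-sampling, and day-wise parameter correlation matrices.
* **State models** — day-level composite mood (positive and reflected
  negative mood), and mixed-effects models of repetition, diagnosis and
  within/between-person mood effects with Satterthwaite degrees of freedom
  (lmerTest).
* **Synthetic cohort** — a generator that emulates the study's
  statistical structure (group-dependent compliance, AR(1) mood with
  configurable coupling to gain-domain risk tolerance, repetition drift, a
  stable group offset in log discount rate, controllable between/within
  variance ratios) so the full pipeline runs and is tested without any
  human data.

## Worked example

```r
library(daypref)

cfg <- cohort_config(n_patients = 6, n_controls = 6, n_days = 8, seed = 42)
res <- run_pipeline("artifacts", config = cfg, seed = 42, verbose = FALSE)

subset(res$icc, resolution == "day", c(parameter, icc, n_observations))
#>       parameter        icc n_observations
#> 1 risk_tol_gain 0.15243865             54
#> 2 risk_tol_loss 0.09152912             63
#> 3  amb_tol_gain 0.34322149             54
#> 4  amb_tol_loss 0.28617169             63
#> 5     log_kappa 0.27449203             55
```

Each row decomposes the day-to-day variation of one reported-scale
parameter: `icc` is the share of variance attributable to stable
between-person differences. At this deliberately tiny demonstration scale
(12 subjects, 8 days) the per-day estimation noise keeps all ICCs low;
at study scale the latent parameters carry ICCs of roughly 0.4-0.67,
discounting being the most trait-like.

```r
subset(res$lme, model == "mood" & term == "mood_within")
#>          term  estimate          se       ci_lo      ci_hi        t       df           p     parameter model   coding
#> 9 mood_within 0.0216873 0.006918513 0.007661318 0.03571328 3.134676 36.40486 0.003393803 risk_tol_gain  mood control0
```

The within-person mood coefficient says that on days a subject reports
better-than-usual composite mood (0-100 scale), their gain-domain risk
tolerance (α − 1) is higher by about 0.022 per mood point — the
state-dependence effect the pipeline is designed to detect, here recovered
from a synthetic cohort generated with a true coupling of 0.02.

A thin command-line wrapper with `design` / `simulate` / `fit` /
`decompose` / `state` / `run` subcommands is installed at
`inst/cli/daypref.R`.

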