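# structbayes

Hierarchical Bayesian modelling and analysis of **structure learning in
sensorimotor integration**: how people reaching under a hidden visuomotor
shift learn not just the mean of the perturbation but its *correlation
structure*, and exploit it when visual feedback is only partially
informative.

The package is aimed at computational/sensorimotor researchers who want to
simulate the model, regenerate its figure-level predictions, or run the
same behavioural analyses on their own per-trial data.

## The model

On each trial a hidden shift $s = (s_h, s_v) \sim \mathcal{N}(\mu, \Sigma)$
(with $\mu = (-1, +1)$ cm, unit SDs, correlation $\rho$) displaces the
displayed hand position; mid-movement feedback $d$ is modelled as
$p(d \mid s) = \mathcal{N}(d; s, \Sigma_\text{obs})$ with diagonal
$\Sigma_\text{obs}$ set by the feedback condition (full, partial-h,
partial-v, none). Ideal integration is the conjugate Gaussian posterior
$\Sigma_p = (\Sigma^{-1}+\Sigma_\text{obs}^{-1})^{-1}$,
$\mu_p = \Sigma_p(\Sigma_\text{obs}^{-1}d + \Sigma^{-1}\mu)$.

The simulated participant does not know $(\mu, \Sigma)$: it holds a
normal-inverse-Wishart belief over them, updated in closed form after every
full-feedback trial, and responds *bounded-rationally* by rejection
sampling a shift from its posterior belief and compensating it
($\tilde r = -\tilde s$). Learning the covariance makes the
uninformative-dimension slope of partial-feedback trials fall over
sessions, and makes no-feedback endpoints correlated — the two signatures
the analysis pipeline quantifies.

## Worked example

Simulate two six-participant cohorts (correlated vs uncorrelated training,
4 sessions x 1000 trials each) and compare their last-session behaviour:

```r
library(structbayes)

rep <- reproduce_study(run_config(groups = c("correlated", "uncorrelated"),
                                  n_participants = 6, seed = 1))
glance(rep)
#> # A tibble: 2 x 5
#>   group        partial_slope mean_h mean_v xy_corr
#>   <chr>                <dbl>  <dbl>  <dbl>   <dbl>
#> 1 correlated           0.607  0.837 -0.833 -0.531
#> 2 uncorrelated         0.938  0.808 -0.781 -0.0958
```

Reading the row for the correlated cohort: after four sessions the median
robust slope of terminal deviation against true shift in the
*uninformative* dimension of partial-feedback trials has fallen to 0.61
(1 = no use of feedback, 0 = full compensation), while the uncorrelated
cohort stays near 0.94 — only training under the correlation teaches the
model to transfer feedback across dimensions. Both cohorts compensate the
mean shift about equally well (`mean_h`/`mean_v` near the ideal +1/-1 cm),
and only the correlated cohort develops a clearly negative correlation
between the horizontal and vertical no-feedback endpoints (-0.53), the
signature of responding by sampling from a correlated belief.

Individual pieces compose with the pipe:

```r
grp <- group_config("correlated")
records <- simulate_cohort(grp, actor_config(), n_participants = 6, seed = 1)

records |>
  sliding_series("slope", "PARTIAL_UNINF", window = 100)   # one participant
records |>
  cohort_series("xy_corr", "NONE", window = 50) |>
  autoplot()

robust_line(records$s_v, records$dev_v) |> tidy()
```

`import_trials()` + `import_mapping()` bring foreign per-trial tables (CSV,
any column names/units) into the same record format, after which every
analysis above applies unchanged.

## Package layout

- `R/integration.R` — conjugate Gaussian cue combination, ideal actor
- `R/learner.R` — NIW belief, conjugate updates, rejection-sampling actor
- `R/experiment.R` — schedules, shift draws, virtual participants
- `R/analysis.R` — robust slopes, sliding windows, endpoint/carryover
  statistics, nonparametric tests
- `R/io.R`, `R/reproduce.R` — record CSV round-trip, import mappings,
  run configs, reproduction driver, grid-search fitting
- `vignettes/structure-learning.Rmd` — the model, its assumptions, and all
  methodological choices
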