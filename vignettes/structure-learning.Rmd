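---
title: "Structure learning in Bayesian sensorimotor integration: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure learning in Bayesian sensorimotor integration: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structbayes)
```

## The task and its statistical structure

The package models a visuomotor reaching task in which the displayed
("virtual") hand position is translated, on every trial, by a hidden 2-D
shift $s = (s_h, s_v)$ in the vertical plane at the target depth. The shift
is bivariate Gaussian,

$$ s \sim \mathcal{N}(\mu, \Sigma), \qquad
   \mu = \begin{pmatrix} -1 \\ +1 \end{pmatrix}\text{cm}, \qquad
   \Sigma = \begin{pmatrix} \sigma_1^2 & \rho\sigma_1\sigma_2 \\
                            \rho\sigma_1\sigma_2 & \sigma_2^2 \end{pmatrix}, $$

with $\sigma_1 = \sigma_2 = 1$ cm. The correlation $\rho$ is the *structural
invariant*: one training group experiences $\rho = -0.999$ (a leftward jump
is always an upward jump), a control group $\rho = 0$. Everything downstream
— what an observer can infer from partial feedback, and what is worth
learning — hinges on $\rho$.

Mid-movement visual feedback $d$ of the shifted position comes in four
reliabilities, modelled through a Gaussian likelihood
$p(d \mid s) = \mathcal{N}(d; s, \Sigma_\text{obs})$ with diagonal
$\Sigma_\text{obs}$: *full* feedback (a precise cursor; both variances low),
two *partial* conditions (an elongated bar, precise in one dimension and
uninformative along its long axis), and *no* feedback. The package carries
two noise profiles: the exact-limit profile (`high = Inf`, zero precision in
an uninformative dimension) used for ideal-actor algebra, and the finite
profile `low = 0.2`, `high = 40` cm$^2$ used by the simulated learner, whose
generative model needs finite densities for its acceptance step.

All positions are expressed in *deviation coordinates*: the target centre is
the origin, a trial's terminal deviation is `true shift + response`, and a
perfect compensation is the zero vector. A hit is a terminal deviation of
norm at most 0.8 cm (cursor radius 0.3 cm plus target radius 0.5 cm).

## Bayesian integration and the performance slope

With Gaussian prior and likelihood the posterior over the shift is Gaussian
with precision-form moments

$$ \Sigma_p = (\Sigma^{-1} + \Sigma_\text{obs}^{-1})^{-1}, \qquad
   \mu_p = \Sigma_p(\Sigma_\text{obs}^{-1} d + \Sigma^{-1}\mu). $$

`posterior_belief()` implements exactly this, handling infinite variances as
zero precision so the no-feedback condition returns the prior *exactly*
rather than approximately. An ideal actor responds with $-\mu_p$.

The behavioural readout is the *performance slope*: regressing terminal
deviation on the true shift, dimension by dimension. Slope 0 means
feedback-driven compensation, slope 1 pure reliance on the prior mean. For
the ideal actor the slope in dimension $k$ is
$1 - (W\Sigma)_{kk}/\Sigma_{kk}$ with feedback weight
$W = \Sigma_p \Sigma_\text{obs}^{-1}$ (`ideal_slope()`); the term involving
the off-diagonal of $W$ is what makes the *uninformative* dimension of a
partial-feedback trial diagnostic of structure knowledge — with full
knowledge of $\rho$ the uninformative-dimension slope is $1-\rho^2 \approx
0$, with $\rho = 0$ it is 1.

## The hierarchical learner

Participants do not know $(\mu, \Sigma)$; the model learns them. Because a
full-feedback observation has marginal likelihood
$\mathcal{N}(d; \mu_0, \Sigma_0 + \Sigma_\text{obs})$, the learner places a
normal-inverse-Wishart (NIW) prior on $(\psi, \Theta) =
(\mu_0, \Sigma_0 + \Sigma_\text{obs})$ and updates it in closed form after
each full-feedback trial (`train_on_trial()`, `niw_update_batch()`):
$m_N = (\kappa_0 m_0 + N\bar D)/\kappa_N$, $\kappa_N = \kappa_0 + N$,
$\nu_N = \nu_0 + N$, and $S_N$ accumulates the empirical scatter plus a
between-means term. Sequential and batch updates commute, which the tests
exercise as a permutation-invariance property.

Initial values are `m0 = (0, 0)`, `kappa0 = 300`, `nu0 = 3000`,
`S0 = diag(nu0, nu0)` — a diagonal unit-variance covariance belief. The
pseudo-count weights set the learning rates: the mean is learned within a
few hundred trials, the covariance (hence $\rho$) over thousands, matching
the multi-session time course of the behaviour. `grid_search_fit()` exposes
the simulated-matching procedure for these two weights; since no canonical
grid is prescribed, its bounds and resolution are caller-supplied.

### Bounded-rational responses by rejection sampling

Rather than responding with the posterior mode, the simulated participant
*samples* its belief. Each rejection-loop iteration: draw
$(\tilde\psi, \tilde\Theta)$ from the current NIW; set
$\tilde\mu_0 = \tilde\psi$, $\tilde\Sigma_0 = \tilde\Theta -
\Sigma_\text{obs}^\text{full}$ (always the full-feedback noise, since
training is on full-feedback trials only); discard and restart unless
$\tilde\Sigma_0$ is positive definite (the PSD gate, with a $10^{-12}$
eigenvalue floor against numerically zero eigenvalues); draw
$\tilde s \sim \mathcal{N}(\tilde\mu_0, \tilde\Sigma_0)$; accept with
probability $p(d \mid \tilde s)/l_\text{max}$ and respond $-\tilde s$.

Two numerical choices deserve note:

* **The likelihood peak.** $l_\text{max}$ is taken as the exact maximum of
  the bivariate Gaussian density,
  $1/(2\pi\sqrt{\lvert\Sigma_\text{obs}\rvert})$. Any constant at least as
  large as the true peak leaves the accepted distribution unchanged — the
  choice affects only efficiency — so the exact peak is used as the most
  efficient valid bound.
* **No-feedback trials.** With the finite $(40, 40)$ cm$^2$ noise the
  acceptance step needs *some* nominal feedback point; the default uses the
  trial's (unseen) true shifted position, consistent with the generative
  model. At variance 40 cm$^2$ the acceptance surface is nearly flat, so
  this is behaviourally negligible; `actor_config(none_acceptance =
  "skip")` omits the step entirely instead.

**Termination.** The accepted-sample law of a rejection loop does not
depend on how many proposals were consumed, so the loop is memoryless. On
rare trials the feedback point falls 3.5+ SD out in the prior-predictive
tail and the per-proposal acceptance rate drops below $10^{-6}$; running
the literal loop to completion there is computationally hopeless. After
`max_iter` proposals (default $10^6$) the trial is therefore completed with
a distribution-preserving equivalent: a PSD-gated hyper-parameter draw,
importance-resampled by its marginal acceptance weight
$\mathcal{N}(d; \mu_0, \Sigma_0 + \Sigma_\text{obs})$, followed by an exact
draw from the closed-form conjugate posterior — the same factorisation the
sampler-correctness tests verify. With the study's pseudo-counts the
resampling weights are nearly constant across draws, so a 4096-draw pool is
ample. `actor_config(on_cap = "error")` restores a hard failure instead.
All 2x2 linear algebra on this hot path (Bartlett inverse-Wishart draws,
Cholesky factors, inverses) is scalar-vectorised; `stats::rWishart` serves
as an independent cross-check in the tests, not as the implementation.

### Sampling and carryover as explanations of endpoint correlation

A mean-compensating ideal actor produces *constant* no-feedback endpoints
(up to isotropic motor noise), hence no correlation between their
horizontal and vertical components. A belief-sampling actor reproduces the
learnt correlation in its endpoint scatter. Trial-by-trial carryover from
the preceding full-feedback shift is a second, non-exclusive source of
structured endpoint variability; `simulate_human_like()` exists precisely
so the pipeline's `carryover_correlation()` (Pearson correlation with a
permutation p-value) can be validated against known generating weights.

## The experiment simulator

`schedule_session()` reproduces the study layout: 4 sessions of 1000
trials; session 1 opens with a three-stage training phase (50 no-shift
trials with a veridical cursor, 50 fully visible shifted-cursor trials, 100
ordinary full-feedback trials); main-phase conditions are independent draws
with probabilities 1/2 (full) and 1/6 each (partial-h, partial-v, none).
Test-trial shifts are correlated ($\rho=-0.999$) for *every* group; only
full-feedback training shifts differ between groups. The instructed group
flags full-feedback trials that immediately precede a no-feedback trial as
uncorrelated insertions with per-opportunity probability $0.96 =
0.08/(1/2 \cdot 1/6)$, so flagged trials are about 8% of all trials and
structurally never precede a partial-feedback trial. The no-auditory group
differs only in a recorded flag: the model has no reward-learning pathway,
and the flag exists so analyses can stratify.

Scaled-down sessions (used throughout the test suite to keep runtimes
modest) shrink the training stages proportionally; the defaults are the
full study sizes. When reduced problem sizes are used for a specific
result, the call states them explicitly (e.g. the grid-search recovery
check runs 1 session of 400 trials with 2 runs per cell on a coarse
log-spaced grid; the cohort-level behavioural checks always run the full
6 participants x 4 x 1000 per group).

Seeding follows a single top-level seed expanded into per-participant
streams by a fixed multiplicative hash (`seed`, participant index), so
cohorts are replayable participant by participant and grid-search cells
are seeded by their parameter values, independent of evaluation order.

### What the generator does and does not emulate

The simulator reproduces the study's *design* (shift statistics, condition
proportions, session structure, hit rule) and the model's response process.
It does not emulate: within-trial kinematics or timing, reaction to binary
reward feedback (no reinforcement pathway), display details of the bar
stimulus, trial repetition after timeouts, or perceptual noise added to the
display — the feedback point equals the true shifted position, and all
feedback uncertainty lives in the actor's $\Sigma_\text{obs}$, exactly as
in the model being simulated. Passing tests therefore validate the
*model-side* account; they cannot certify that human data contain no
processes outside it.

## The analysis pipeline

* **Robust slopes.** `robust_line()` is IRLS with Tukey bisquare weights at
  tuning constant 4.685 and MAD/0.6745 scale (delegated to `MASS::rlm`,
  iteration cap 50, weight tolerance $10^{-8}$); with no point beyond the
  tuning radius every weight is one and the fit equals ordinary least
  squares. Exactly constant responses return slope 0 directly, since a zero
  robust scale makes IRLS degenerate.
* **Windowing.** All sliding statistics use step 1 over the *filtered*
  subsequence of relevant trials, pooled across sessions; a window is
  labelled with the session of its median trial. Defaults: slope and mean
  windows 100 trials, endpoint-correlation windows 50 (both are
  parameters, since different figure-level analyses use 50 or 100).
* **Pooling the uninformative dimension.** The structure-learning index
  pools the vertical dimension of partial-h trials with the horizontal
  dimension of partial-v trials. Because the mean shift differs in sign
  between dimensions (+1/-1 cm), raw pooling would contaminate the slope
  with a between-type component; each fitted window therefore centres
  `s` and `dev` per partial type (a type fixed effect) before the robust
  fit. Unpooled per-dimension series are exposed alongside.
* **Endpoint statistics.** No-feedback means are reported in absolute
  compensation coordinates (ideal = +1/-1 cm); the endpoint correlation
  gets a Fisher-z 95% CI (the appropriate large-sample interval; no claim
  is made that the original error bars used the same construction).
  Degenerate zero-variance endpoints flag the correlation as missing
  rather than returning a spurious value.
* **Tests.** `group_compare()` wraps the signed-rank, rank-sum and sign
  tests with exact small-sample p-values where available ($n \le 25$, no
  ties); ties fall back to mid-rank normal approximations and say so. No
  multiple-testing correction is applied, and the output notes this.
* **Session-1 training trials** are excluded from condition statistics
  (stages 1–2 are not ordinary trials at all; stage 3 is full-feedback
  only), while the learner still trains on them by default
  (`train_during_training_phase`), since the simulated participant
  experiences them as full-feedback exposure.

## Known limitations

The learner acquires structure only from full-feedback trials; groups whose
empirical learning depends on reward feedback (the uncorrelated group's
test-phase experience, the no-auditory manipulation) are represented by
their schedules, not by a reward-sensitive model. The rejection sampler's
iteration count is reported per trial but is not a model of response time.
Imports of deposited behavioural data rely on a user-supplied column
mapping because no canonical layout is assumed; the import path is
validated against synthetic round-trips.
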