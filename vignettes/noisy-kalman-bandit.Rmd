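---
title: "Learning and choice variability under uncertainty: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning and choice variability under uncertainty: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`noisybandit` implements a complete simulation-and-inference pipeline for
studying how two sources of decision variability — imprecise value learning
and exploratory choice — behave under expected uncertainty (reward
stochasticity) and unexpected uncertainty (reward volatility) in a
two-armed bandit. This vignette describes the models, the task generator,
the estimation machinery, and the design decisions behind them.

## The task

Three conditions share a common construction. Rewards are integer points in
[1, 99] and the two options are symmetric: the generative means satisfy
$\bar r_2(t) = 100 - \bar r_1(t)$ on every trial.

* **Ref** (reference): five short rounds per 80-trial block (lengths a
  permutation of 8, 12, 16, 20, 24), each round a fresh option pair with a
  static generative mean.
* **S+** (high stochasticity): the Ref schedule with its static means
  shrunk multiplicatively toward 50, so that reward variability is
  unchanged while discriminability falls.
* **V+** (high volatility): 80-trial blocks in which the generative mean
  drifts as a bounded random walk and the options' means cross at
  *reversals*.

The generator mirrors the construction end to end:

1. **Walks.** Candidate mean trajectories are random walks started at 50
   whose marginal step distribution is a moment-matched beta on the 1–99
   range centered on the previous value with SD 5 points. Walks leaving
   [10, 90] or stepping more than 10 points are discarded; about 1% of raw
   walks survive, so the pool is grown in batches until every excursion
   length is available.
2. **Excursions.** A maximal run of consecutive values strictly above or
   strictly below 50 is an *excursion*; runs of exactly 8, 12, 16, 20 and
   24 trials are drawn from the pool. Each V+ block concatenates five of
   them in random order with forced side alternation (values mirrored
   through 50 where needed), so means cross at all four junctions. Each Ref
   block uses the same excursions' mean rewards as its static round means.
3. **Calibration.** The reward SD (shared by all conditions) is solved so
   that 75% of integer rewards drawn from the better option of the Ref
   rounds exceed 50 points, pooling over rounds weighted by length. The
   exceedance probability is computed exactly from the beta tail (an
   integer reward above 50 corresponds to a continuous draw of at least
   50.5 before rounding), and the root is found to a $10^{-4}$ SD
   tolerance.
4. **Difficulty matching.** The S+ means are obtained by shrinking the Ref
   means toward 50 in 1% multiplicative steps until the simulated accuracy
   of a greedy Kalman filter (variances set to the schedule's effective
   generative values, rewards resampled each run) matches its accuracy on
   the V+ schedule within 0.5 percentage points. Accuracy is monotone in
   the shrink count, so the stopping point on the 1%-grid is located by
   bisection; each evaluation simulates 10,000 runs.

Generated schedules typically calibrate to a reward SD of 11–14 points and
an effective sampling variance of 0.013–0.020 on the 0–1 scale, bracketing
the fixed model constant 0.0163 described below.

## The learning agent

All values are rescaled to [0, 1] (points / 100). The agent tracks the
posterior mean $x^o_t$ and variance $v^o_t$ of both options, initialized to
0.5 and $v_0 = 0.0214$ at the start of every Ref/S+ round and every V+
block (reversals are covert, so no reinitialization occurs within a V+
block). After choosing option $c$ and observing reward $r$:

$$x^c_{t} = x^c_{t-1} + k_t\,(r_{t-1} - x^c_{t-1}) + \varepsilon_t,
\qquad k_t = \frac{v^c_{t-1}}{v^c_{t-1} + v_s},$$

with sampling variance fixed at $v_s = 0.0163$, variance update
$v^o_t = (1 - k^o_t)\,v^o_{t-1} + v_d$ (gain 0 for the unobserved option),
and *learning noise* $\varepsilon_t \sim \mathcal N(0, \eta_t^2)$ whose SD
follows Weber scaling: $\eta_t = \zeta\,\lvert k_t (r_{t-1} -
x^c_{t-1})\rvert$. The unchosen option's value decays toward the 0.5
baseline at rate $\delta$: $x^u_t = x^u_{t-1} + \delta(0.5 - x^u_{t-1})$
(the agent is written with the decay applied to the previous value; the
same-trial indexing that appears in some statements of the decay rule is
not self-consistent). Choices follow a softmax on the value difference with
temperature $\tau$, $p^1_t = [1 + e^{-(x^1_t - x^2_t)/\tau}]^{-1}$, with
$\tau \to 0$ the greedy argmax (fair coin on ties).

The drift variance is parameterized by its *asymptotic Kalman gain*
$\alpha$ — the steady-state gain for an option chosen on every trial —
through $v_d = \alpha^2 v_s / (1 - \alpha)$, the closed form of the
variance recursion's fixed point. Four free parameters result: $\alpha \in
(0,1)$, $\zeta \ge 0$, $\delta \in [0,1]$, $\tau \ge 0$.

Design notes: posterior means are not clipped after noise (the softmax is
well defined regardless); learning noise does not feed back into the
posterior variance (the agent is blind to its own imprecision); decay
applies once per trial to the unchosen option only. The *optimal agent* for
a condition is the same filter with $\zeta = \delta = \tau = 0$ and
variances set to the schedule's effective generative values.

## Likelihood and fitting

With $\zeta > 0$ the latent value trajectory is stochastic, so the choice
likelihood marginalizes over it. A bootstrap particle filter propagates
particles holding $(x^1, x^2)$ through the noisy update for each observed
choice and reward, weights them by the softmax probability of the observed
choice, and resamples systematically when the effective sample size falls
below half the particle count. Posterior variances are deterministic given
the choices and are tracked once outside the particle set. At $\tau = 0$ a
trial's marginal probability can underflow; it is floored at
$1/(2N)$ for $N$ particles. At $\zeta = 0$ the filter reproduces the exact
closed-form likelihood to machine precision, which the test suite uses as
an oracle; a short-session brute-force Monte-Carlo marginalization provides
the oracle for $\zeta > 0$.

Fitting maximizes the particle-filter log-likelihood with Nelder–Mead on
bound-transformed coordinates ($\alpha \in [0.001, 0.999]$ and $\delta \in
[0,1]$ via logistic maps; $\zeta \in [10^{-3}, 2]$ and $\tau \in [10^{-4},
1]$ searched in log space). Particle streams are frozen per restart
(common random numbers), making the objective deterministic within a
restart. The likelihood is nearly flat along a ridge that trades learning
noise against choice temperature, and random starts alone frequently
collapse $\hat\zeta$ to zero; the fitter therefore first fits the
no-noise variant exactly and launches ladder restarts from that solution
at $\zeta \in \{0.1, 0.4, 1.0\}$, plus random starts. Restart solutions
are compared under one common set of particle streams — comparing them on
their own frozen seeds would select lucky seeds rather than better
parameters — and the winner is re-evaluated at a higher particle count,
because the filter's log-likelihood estimate is biased low by roughly half
its variance, which matters when it is compared against the exactly
computed no-noise model. Point estimation (with restarts) replaces
posterior approximation throughout: point estimates are what all
downstream analyses consume.

## Model comparison and recovery

Three candidate models are compared: the full model, the no-learning-noise
variant ($\zeta = 0$) and the greedy variant ($\tau = 0$). Per-subject
evidence is a penalized log-likelihood, $\log \hat L - (k/2)\log n$, and
population-level comparison uses random-effects Bayesian model selection:
a variational Dirichlet update over model frequencies iterated to
$10^{-6}$, with exceedance probabilities computed exactly through the Beta
CDF for two models and by $10^5$ Monte-Carlo draws otherwise.

The information-criterion penalty is harsher than a Bayesian evidence for
weakly identified parameters: at 160 trials the full model's likelihood
advantage from a realistic amount of learning noise (1–2 nats) cannot buy
back the extra-parameter penalty ($\tfrac12\log 160 \approx 2.5$ nats).
The default model-recovery study therefore simulates 480-trial sessions
(three reward-resampled copies of the two-block schedule) from a
generating population with clearly expressed noise and exploration
($\zeta$ around 0.9–1.1, $\tau$ around 0.07), and reports the confusion
matrix whose rows are exceedance-probability vectors of cohorts generated
from each candidate. Parameter recovery is summarized by Spearman
correlations and median signed errors between generating and recovered
values.

## Reward costs

The *reward excess* of an agent on a schedule is the mean obtained-minus-
foregone reward per trial (both options' rewards are realized on every
trial; the agent observes only the chosen one). The marginal cost of a
variability source is the fractional loss of excess relative to the same
agent with that source removed, $C_x(g) = 100\,(1 - E(g)/E(0))$, so
$C_x(0) = 0$ and a purely random agent approaches 100%. Cost baselines are
fragile on a single reward realization of a hard schedule (the S+ excess
can be within Monte-Carlo noise of zero), so cost evaluations pool several
task sets and several fresh reward draws per schedule.

Two matched-across-conditions base profiles are used for the directional
comparisons. The learning-noise channel is evaluated without decay
($\alpha = 0.5$, $\delta = 0$, $\tau = 0.055$): decay is itself a
forgetting process, and at $\delta \gtrsim 0.05$ it absorbs the cost of
imprecise updates, masking the volatility-specific cost of learning noise.
The exploration channel is evaluated at cohort-typical decay ($\delta =
0.2$), where cost curves are monotone; without decay, exploration in the
volatile condition is genuinely informative (choosing the drifting,
unchosen option reveals its reward) and the cost curve can dip below zero
at small temperatures. Under these profiles the same learning noise costs
more under volatility, and the same choice temperature costs less under
volatility than under high stochasticity. Cost-curve inversion (the
parameter value producing a fixed loss) interpolates linearly on the
isotonically smoothed curve.

## Statistical layer

Rank-based statistics throughout: Spearman correlations (tie-corrected,
two-sided), partial Spearman correlations (Pearson on ranks after
residualizing on the controls, $t$ reference with $n - 2 - k$ degrees of
freedom), Benjamini–Hochberg FDR control at 0.05 over the 66 unique cells
of the 12-parameter correlation matrix, and Wilcoxon tests for group
comparisons. Median splits assign the median subject to the lower half.

PCA operates on the standardized subjects × 12 matrix (4 parameters × 3
conditions). Percent variance explained sums to 100 over the 12 PCs;
per-condition variance explained is the mean $R^2$ of the condition's four
standardized columns regressed on the PC score (equivalently
$w_{ij}^2\lambda_j$ for standardized data — this is the normalization used
for the per-parameter coefficient of determination as well). Bootstrap
resamples (1000 by default) are re-aligned to the full-sample solution by
maximal absolute loading correlation with sign flipping, removing the
order/sign indeterminacy of eigenvectors; the shuffle null permutes every
column independently before each decomposition, and significance is the
one-sided comparison of bootstrapped against shuffled variance explained.

The exclusion rule and the bonus bound use exact binomial tails: a subject
is kept only if accuracy exceeds chance at one-tailed $\alpha = 0.05$ in
all three conditions, and the above-chance accuracy bound at 480 trials is
258/480 = 53.75%. The a-priori power of a correlation test uses the
Fisher-z approximation; $\rho = 0.20$ at $n = 200$ gives 81% power at
two-sided $\alpha = 0.05$.

## The synthetic cohort

No participant data ships with the package; a synthetic cohort generator
stands in for it. Per-parameter population distributions are log-normal
($\zeta$, $\tau$) or logit-normal ($\alpha$, $\delta$) on latent Gaussian
scales. The default cohort emulates the qualitative structure of human
fits: higher learning rate and choice temperature and lower learning noise
under volatility ($\alpha$ centered at 0.25 in Ref/S+ vs 0.45 in V+;
$\zeta$ at 0.45 vs 0.32; $\tau$ at 0.055 vs 0.085; $\delta$ at 0.35
throughout), a cross-condition latent correlation of 0.5 per parameter,
and latent correlations of $-0.4$ between learning noise and learning rate
and $+0.4$ between temperature and learning rate. A wide, condition-
constant `"recovery"` population spans the fitting bounds for recovery
studies, and a `"strong"` population expresses both variability sources
clearly for model recovery. Each subject receives a freshly generated,
difficulty-matched task set by default.

What the generator does *not* emulate: sequential effects beyond the model
(win-stay biases, lapses), reaction times, learning across blocks,
condition-order effects, and any departure of human behavior from the
noisy Kalman filter itself. Passing tests therefore validate the
*machinery* — generator, likelihood, fitting, selection, statistics — not
claims about human data.

## Problem sizes and reproducibility

The package's own studies run at desk scale: cohorts of 30–50 subjects,
two 80-trial blocks per condition, 500–1000 particles with 4–5 optimizer
restarts per fit, 8 subjects per generating model in model recovery, a few
hundred simulated traversals per cost grid point, and 1000 bootstrap
resamples. Every driver accepts a single seed from which all stage seeds
derive; rerunning a driver with the same seed reproduces its outputs
exactly. Degenerate inputs fail loudly rather than silently: reward
distributions whose moments violate the beta bound, calibration targets
outside the achievable bracket, difficulty-matching targets above the
unshrunk accuracy or unreachable before the means hit 50, cost baselines
without positive excess, and single-round sessions are all errors.

## Known limitations

* Learning noise and choice temperature trade off along a shallow
  likelihood ridge at 160 trials per condition; $\hat\zeta$ and
  $\hat\delta$ recover with rank correlations around 0.4–0.6 there, versus
  0.7–0.9 for $\hat\alpha$ and $\hat\tau$.
* The penalized-likelihood evidence proxy is conservative toward the full
  model at small trial counts (see above); any per-subject evidence column
  can be supplied to `bms()` in its place.
* The cost-directionality results are regime-dependent (decay masks the
  noise channel); the package exposes the base profiles explicitly rather
  than asserting a universal ordering.
* Exceedance probabilities for more than two models are Monte-Carlo
  estimates; at $10^5$ draws their resolution is about $\pm 0.003$.
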