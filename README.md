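# noisybandit

Decision variability under uncertainty has two distinct sources: *exploration*
(probabilistically choosing options that do not maximize expected value) and
*learning imprecision* (random noise corrupting the value updates
themselves). `noisybandit` is an R package for studying how these two sources
behave under expected uncertainty (reward stochasticity) and unexpected
uncertainty (reward volatility) in a restless two-armed bandit, using
simulation of noisy learning agents and likelihood-based model fitting. It is
aimed at computational cognitive modellers who want a complete, tested
pipeline: task generation, agents, particle-filter inference, model
selection, recovery analyses, reward-cost simulations and the accompanying
statistics.

## The model

Option values are tracked by a Kalman filter on the 0–1 reward scale. After
choosing option *c* and observing reward *r*:

    x_c <- x_c + k (r - x_c) + eps,   k = v_c / (v_c + v_s),   eps ~ N(0, eta^2)

with Weber-scaled learning noise `eta = zeta * |k (r - x_c)|`, variance
updates `v_o <- (1 - k_o) v_o + v_d`, decay of the unchosen value toward
baseline `x_u <- x_u + delta (0.5 - x_u)`, and a softmax choice policy with
temperature `tau` (greedy argmax as `tau -> 0`). The drift variance is
parameterized by its asymptotic Kalman gain `alpha` via
`v_d = alpha^2 v_s / (1 - alpha)`; the sampling variance `v_s = 0.0163` and
initial posterior variance `v0 = 0.0214` are fixed scaling constants. The
four free parameters are `alpha`, `zeta`, `delta`, `tau`.

Because learning noise makes the value trajectory latent, choice likelihoods
are estimated by a bootstrap particle filter (exact at `zeta = 0`), and
fitting uses derivative-free optimization with frozen particle streams and
warm-start ladders. Model comparison uses penalized likelihoods with
random-effects Bayesian model selection (Dirichlet parameterization,
exceedance probabilities).

## Task conditions

Three matched conditions per synthetic "participant": **Ref** (short rounds,
static means), **S+** (static means shrunk toward 50 until a greedy Kalman
filter's accuracy matches the volatile condition — higher expected
uncertainty), and **V+** (means drift as bounded random walks and cross at
reversals — unexpected uncertainty). Rewards are integers in 1–99 with the
sampling SD calibrated so 75% of better-option rewards in Ref exceed 50
points.

## Worked example

```r
library(noisybandit)
set.seed(1)

# a matched task set: 2 blocks x 80 trials per condition
ts <- generate_task_set()
ts
#> <nb_taskset> 480 trials; sampling_sd=13.70 pts; V+ optimal accuracy=0.587 (matched in 193 iters)

# simulate a noisy agent on the volatile condition and summarize
p <- agent_params(alpha = 0.4, zeta = 1.0, delta = 0.3, tau = 0.05)
ses <- run_session(p, ts$blocks[ts$blocks$condition == "V+", ])
unlist(summarize_session(ses))
#>    accuracy switch_rate 
#>   0.6062500   0.2531646

# particle-filter likelihood of the simulated choices, and a fit
pf_loglik(ses, p, n_particles = 1000)$loglik
#> [1] -70.06184
fit <- fit_subject(ses, model = "full", n_particles = 1000, n_restarts = 4,
                   seed = 2)
fit
#> <nb_fit full> loglik=-70.00 (mc_se=0.153) alpha=0.269 zeta=1.090 delta=0.204 tau=0.0498
```

The accuracy (0.61) sits well below the optimal agent's (0.66 here) because
of the agent's learning noise and exploration, and the fit recovers the two
variability parameters (`zeta` 1.09 vs 1.0, `tau` 0.0498 vs 0.05; `alpha`
and `delta` are less constrained by a single 160-trial session). Across a
cohort, recovery quality is summarized by `parameter_recovery()`.

The `analysis/` directory holds the numbered study drivers (each takes an
optional seed argument and writes plain-text tables under `results/`):

    01_generate_task.R        schedule generation and statistics
    02_simulate_cohort.R      synthetic cohort, exclusion, behavior curves
    03_fit_models.R           full-model fits + parameter recovery
    04_model_selection.R      BMS and the model-recovery confusion matrix
    05_reward_costs.R         marginal/joint reward costs and inversion
    06_parameter_structure.R  correlation matrix, shuffle null, PCA

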