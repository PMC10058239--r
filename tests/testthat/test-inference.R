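# Particle-filter likelihood and per-subject fitting.

test_that("particle filter equals the closed-form likelihood when learning is noise-free", {
  ts <- test_taskset()
  blocks <- ts$blocks[ts$blocks$condition == "Ref", ]
  set.seed(31)
  for (i in 1:5) {
    p <- agent_params(alpha = runif(1, 0.1, 0.9), zeta = 0,
                      delta = runif(1), tau = runif(1, 0.02, 0.3))
    ses <- run_session(p, blocks)
    ex <- exact_loglik_nonoise(ses, p)
    pf <- pf_loglik(ses, p, n_particles = 200, n_replicates = 2)
    expect_equal(pf$loglik, ex, tolerance = 1e-12)
    expect_equal(pf$mc_se, 0)
  }
})

test_that("the first trial of a round with equal initial values has likelihood 0.5", {
  b <- toy_blocks(n_rounds = 1, len = 1, mean_dev = 20, sd = 5)
  p <- agent_params(alpha = 0.4, zeta = 0, delta = 0, tau = 0.1)
  set.seed(32)
  ses <- run_session(p, b)
  expect_equal(exact_loglik_nonoise(ses, p), log(0.5))
  expect_equal(pf_loglik(ses, p, n_particles = 50)$loglik, log(0.5))
})

test_that("particle filter agrees with brute-force marginalization on a short session", {
  # 5-trial single-round session; oracle: naive Monte-Carlo average of the
  # choice-sequence probability over full latent noise trajectories
  b <- toy_blocks(n_rounds = 1, len = 5, mean_dev = 18, sd = 8)
  p <- agent_params(alpha = 0.5, zeta = 0.5, delta = 0.3, tau = 0.08)
  set.seed(33)
  ses <- run_session(p, b)
  n_mc <- 2e5
  x1 <- rep(0.5, n_mc); x2 <- rep(0.5, n_mc)
  v1 <- p$v0; v2 <- p$v0
  prob <- rep(1, n_mc)
  for (t in 1:5) {
    p1 <- plogis((x1 - x2) / p$tau)
    prob <- prob * (if (ses$choice[t] == 1) p1 else 1 - p1)
    r <- ses$reward[t] / 100
    if (ses$choice[t] == 1) {
      k <- v1 / (v1 + p$v_s)
      up <- k * (r - x1)
      x1 <- x1 + up + rnorm(n_mc, 0, 1) * p$zeta * abs(up)
      v1 <- (1 - k) * v1 + p$v_d
      x2 <- x2 + p$delta * (0.5 - x2)
      v2 <- v2 + p$v_d
    } else {
      k <- v2 / (v2 + p$v_s)
      up <- k * (r - x2)
      x2 <- x2 + up + rnorm(n_mc, 0, 1) * p$zeta * abs(up)
      v2 <- (1 - k) * v2 + p$v_d
      x1 <- x1 + p$delta * (0.5 - x1)
      v1 <- v1 + p$v_d
    }
  }
  oracle <- log(mean(prob))
  pf <- pf_loglik(ses, p, n_particles = 10000, n_replicates = 5)
  tol <- max(3 * pf$mc_se, 0.02)
  expect_equal(pf$loglik, oracle, tolerance = tol / abs(oracle))
})

test_that("particle-filter spread shrinks with the particle count", {
  ts <- test_taskset()
  blocks <- ts$blocks[ts$blocks$condition == "Ref", ]
  p <- agent_params(alpha = 0.4, zeta = 0.6, delta = 0.3, tau = 0.07)
  set.seed(34)
  ses <- run_session(p, blocks)
  spread <- vapply(c(100, 1600), function(np) {
    sd(vapply(1:12, function(i) {
      pf_loglik(ses, p, n_particles = np, n_replicates = 1)$loglik
    }, numeric(1)))
  }, numeric(1))
  # 16x more particles: expect roughly a 4x smaller spread
  expect_lt(spread[2], spread[1] / 2)
})

test_that("log-likelihood is invariant to option relabeling", {
  ts <- test_taskset()
  blocks <- ts$blocks[ts$blocks$condition == "Ref", ]
  p <- agent_params(alpha = 0.45, zeta = 0, delta = 0.25, tau = 0.09)
  set.seed(35)
  ses <- run_session(p, blocks)
  expect_equal(exact_loglik_nonoise(swap_session_options(ses), p),
               exact_loglik_nonoise(ses, p), tolerance = 1e-10)
  pz <- p; pz$zeta <- 0.5
  a <- pf_loglik(ses, pz, n_particles = 2000, n_replicates = 4, seeds = 1:4)
  b <- pf_loglik(swap_session_options(ses), pz, n_particles = 2000,
                 n_replicates = 4, seeds = 1:4)
  expect_equal(a$loglik, b$loglik,
               tolerance = 4 * max(a$mc_se, 1e-3) / abs(a$loglik))
})

test_that("greedy likelihoods floor at the particle resolution instead of -Inf", {
  b <- toy_blocks(n_rounds = 1, len = 6, mean_dev = 30, sd = 3)
  p <- agent_params(alpha = 0.6, zeta = 0, delta = 0, tau = 0)
  set.seed(36)
  ses <- run_session(p, b)
  # force a non-greedy observed choice
  ses$choice[4] <- 3L - ses$choice[4]
  expect_equal(exact_loglik_nonoise(ses, p), -Inf)
  pf <- pf_loglik(ses, p, n_particles = 100)
  expect_true(is.finite(pf$loglik))
  expect_lte(pf$loglik, log(0.5) + 5 * log(1) + log(1 / 200) + 1e-9)
})

test_that("fitting is reproducible and refuses single-round sessions", {
  ts <- test_taskset()
  blocks <- ts$blocks[ts$blocks$condition == "Ref", ]
  p <- agent_params(alpha = 0.35, zeta = 0.4, delta = 0.3, tau = 0.07)
  set.seed(37)
  ses <- run_session(p, blocks)
  f1 <- fit_subject(ses, model = "full", n_particles = 200, n_restarts = 2,
                    maxit = 60, seed = 7)
  f2 <- fit_subject(ses, model = "full", n_particles = 200, n_restarts = 2,
                    maxit = 60, seed = 7)
  expect_equal(f1$params_hat, f2$params_hat)
  expect_equal(f1$loglik, f2$loglik)
  one_round <- ses[paste(ses$block, ses$round) == paste(ses$block[1], ses$round[1]), ]
  expect_error(fit_subject(one_round, model = "full"), "two rounds")
})

test_that("fits recover a low-noise agent's temperature", {
  ts <- test_taskset()
  blocks <- ts$blocks[ts$blocks$condition == "Ref", ]
  blocks <- replicate_block_rewards(blocks, ts$sampling_sd, 3)
  p <- agent_params(alpha = 0.4, zeta = 0, delta = 0.2, tau = 0.05)
  set.seed(38)
  ses <- run_session(p, blocks)
  f <- fit_subject(ses, model = "nozeta", n_restarts = 4, seed = 9)
  expect_lt(abs(log(f$params_hat$tau / 0.05)), log(1.6))
  expect_true(f$converged)
})
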