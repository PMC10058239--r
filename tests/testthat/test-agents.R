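# The noisy Kalman-filter agent: gain parameterization, update equations,
# choice policy, and the optimal-agent construction.

test_that("drift_from_gain matches the numeric fixed point of the variance recursion", {
  v_s <- 0.0163
  fixed_point_gain <- function(v_d) {
    v <- 0.0214
    for (i in 1:10000) v <- (1 - v / (v + v_s)) * v + v_d
    v / (v + v_s)
  }
  for (a in c(0.05, 0.2, 0.5, 0.8, 0.95)) {
    v_d <- drift_from_gain(a, v_s)
    expect_equal(fixed_point_gain(v_d), a, tolerance = 1e-10)
    expect_equal(gain_from_drift(v_d, v_s), a, tolerance = 1e-12)
  }
  # alpha = 0.5 closed form
  expect_equal(drift_from_gain(0.5, v_s), 0.25 * v_s / 0.5)
  # vanishing drift as alpha -> 0
  expect_lt(drift_from_gain(1e-4, v_s), 1e-8)
  expect_error(drift_from_gain(1.2), "alpha")
})

test_that("kalman_gain follows v / (v + v_s)", {
  expect_equal(kalman_gain(0, 0.0163), 0)
  expect_equal(kalman_gain(0.0163, 0.0163), 0.5)
  expect_equal(kalman_gain(0.0214, 0.0163), 0.0214 / 0.0377)
})

test_that("update_chosen applies the noisy Kalman update with Weber-scaled noise", {
  # zeta = 0: deterministic arithmetic, x' = x + k (r - x)
  p <- agent_params(alpha = 0.5, zeta = 0, delta = 0, tau = 0.1,
                    v_s = 0.1, v0 = 0.1)
  st <- init_state(p)
  out <- update_chosen(st, 1, 0.7, p)   # k = 0.1/0.2 = 0.5
  expect_equal(out$state$x[1], 0.6)
  expect_equal(out$trace$k, 0.5)
  expect_equal(out$trace$eta, 0)
  expect_equal(out$state$v[1], (1 - 0.5) * 0.1 + p$v_d)

  # zero prediction error: no change at any zeta
  p2 <- agent_params(alpha = 0.3, zeta = 0.8, delta = 0, tau = 0.1)
  st2 <- init_state(p2)
  out2 <- update_chosen(st2, 2, 0.5, p2)
  expect_equal(out2$state$x[2], 0.5)
  expect_equal(out2$trace$eta, 0)

  # Weber scaling: eta = zeta * |k * pe|
  set.seed(1)
  p3 <- agent_params(alpha = 0.5, zeta = 0.5, delta = 0, tau = 0.1,
                     v_s = 0.1, v0 = 0.1)
  out3 <- update_chosen(init_state(p3), 1, 0.7, p3)  # |k pe| = 0.1
  expect_equal(out3$trace$eta, 0.05)
  expect_equal(out3$state$x[1], 0.6 + out3$trace$eps)
})

test_that("update_unchosen decays toward baseline and inflates variance", {
  p <- agent_params(alpha = 0.3, zeta = 0, delta = 0.3, tau = 0)
  st <- init_state(p)
  st$x[2] <- 0.8
  out <- update_unchosen(st, 1, p)
  expect_equal(out$x[2], 0.71)
  expect_equal(out$v[2], p$v0 + p$v_d)
  # delta = 0 leaves the value untouched; delta = 1 resets it
  p0 <- agent_params(alpha = 0.3, zeta = 0, delta = 0, tau = 0)
  expect_equal(update_unchosen(st, 1, p0)$x[2], 0.8)
  p1 <- agent_params(alpha = 0.3, zeta = 0, delta = 1, tau = 0)
  expect_equal(update_unchosen(st, 1, p1)$x[2], 0.5)
})

test_that("choice_prob is the softmax with a greedy tau = 0 limit", {
  st <- list(x = c(0.5, 0.5), v = c(1, 1))
  expect_equal(choice_prob(st, 0), 0.5)
  expect_equal(choice_prob(st, 0.2), 0.5)
  st$x <- c(0.6, 0.5)
  expect_equal(choice_prob(st, 0.1), 1 / (1 + exp(-1)))
  expect_equal(choice_prob(st, 0), 1)
  st$x <- c(0.4, 0.5)
  expect_equal(choice_prob(st, 0), 0)
  # label-swap symmetry
  sw <- list(x = rev(st$x), v = st$v)
  expect_equal(choice_prob(st, 0.07) + choice_prob(sw, 0.07), 1)
})

test_that("optimal agent outperforms noisy agents on the same schedule", {
  ts <- test_taskset()
  for (cond in c("Ref", "V+")) {
    blocks <- ts$blocks[ts$blocks$condition == cond, ]
    opt <- make_optimal_agent(ts$genspec[[cond]])
    noisy <- opt
    noisy$zeta <- 0.8
    noisy$tau <- 0.15
    set.seed(5)
    acc_opt <- mean(replicate(40, summarize_session(run_session(opt, blocks))$accuracy))
    set.seed(5)
    acc_noisy <- mean(replicate(40, summarize_session(run_session(noisy, blocks))$accuracy))
    expect_gt(acc_opt, acc_noisy)
  }
})

test_that("agent parameters round-trip through JSON with constants recorded", {
  p <- agent_params(alpha = 0.37, zeta = 0.52, delta = 0.21, tau = 0.066)
  q <- params_from_json(params_to_json(p))
  expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
  expect_equal(q$v_s, 0.0163)
  expect_equal(q$v0, 0.0214)
})
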