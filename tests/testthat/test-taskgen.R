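# Schedule generation: bounded walks, excursions, block assembly, reward
# sampling, the 75% calibration rule, effective variances, and difficulty
# matching.

test_that("generated walks respect bounds and the maximum step size", {
  set.seed(11)
  for (i in 1:5) {
    w <- generate_walk(n_steps = 80)
    expect_true(all(w >= 10 & w <= 90))
    expect_true(all(abs(diff(w)) <= 10))
  }
  expect_equal(generate_walk(n_steps = 20, step_sd = 0), rep(50, 20))
})

test_that("walk steps have the configured drifting SD", {
  set.seed(12)
  # nearly unconstrained steps carry the full generative SD of 5 points
  free <- replicate(400, generate_walk(n_steps = 10, bounds = c(5, 95),
                                       max_step = 1e4))
  expect_equal(sd(as.vector(diff(free))), 5, tolerance = 0.2)
  # accepted walks are shrunk by the step/bound rejection rules; frozen
  # against a direct Monte-Carlo estimate (~4.4 points)
  pool <- generate_walk_pool(n_raw = 5000)
  steps <- unlist(lapply(pool, diff))
  expect_gt(length(steps), 500)
  expect_equal(sd(steps), 4.4, tolerance = 0.2)
})

test_that("excursion extraction returns exact-length one-sided segments", {
  # pool with a unique one-sided segment of length 12
  w <- c(rep(49, 3), rep(60, 12), rep(49, 5))
  w <- w + seq(-0.1, 0.1, length.out = length(w))  # break exact ties
  exc <- extract_excursions(list(w), target_lengths = 12)
  expect_equal(exc[[1]]$length, 12)
  expect_true(all(exc[[1]]$values > 50))
  expect_equal(exc[[1]]$mean_reward, mean(exc[[1]]$values))

  # degenerate pool: no one-sided segment of the requested length
  expect_error(extract_excursions(list(rep(50, 30)), target_lengths = 8),
               "one-sided")

  # the full length set against an exhaustive scan of a large pool
  set.seed(13)
  pool <- nb_fixture_env$pool13
  if (is.null(pool)) {
    pool <- generate_walk_pool(n_raw = 8000)
    assign("pool13", pool, envir = nb_fixture_env)
  }
  exc <- extract_excursions(pool)
  expect_equal(vapply(exc, `[[`, numeric(1), "length"), c(8, 12, 16, 20, 24))
  for (e in exc) {
    expect_true(all(e$values > 50) || all(e$values < 50))
  }
})

test_that("V+ blocks concatenate excursions with reversals at every junction", {
  set.seed(14)
  pool <- generate_walk_pool(n_raw = 6000)
  exc <- extract_excursions(pool)
  b <- build_vplus_block(exc, sampling_sd = 10)
  expect_equal(nrow(b), 80)
  expect_equal(sum(b$reversal_flag), 4)
  expect_equal(b$mean_1 + b$mean_2, rep(100, 80))
  # means cross 50 exactly at the flagged junctions
  side <- sign(b$mean_1 - 50)
  expect_equal(which(c(FALSE, diff(side) != 0)), which(b$reversal_flag))
  # single 80-step excursion: no reversals
  e80 <- list(list(values = rep(60, 80) + rnorm(80, 0, 0.1), length = 80,
                   side = "above", mean_reward = 60))
  expect_equal(sum(build_vplus_block(e80, 10)$reversal_flag), 0)
  expect_error(build_vplus_block(exc[1:2], 10), "sum")
})

test_that("Ref blocks use excursion means as static round means", {
  set.seed(15)
  pool <- generate_walk_pool(n_raw = 6000)
  exc <- extract_excursions(pool)
  b <- build_ref_block(exc, sampling_sd = 10)
  expect_equal(nrow(b), 80)
  expect_equal(sort(rle(b$round)$lengths), c(8, 12, 16, 20, 24))
  # zero within-round variance of the generative mean; side preserved
  for (r in unique(b$round)) {
    expect_equal(var(b$mean_1[b$round == r]), 0)
  }
  expect_setequal(round(unique(b$mean_1), 6),
                  round(vapply(exc, `[[`, numeric(1), "mean_reward"), 6))
})

test_that("reward sampling is moment-matched, integer and bounded", {
  set.seed(16)
  r <- sample_rewards(rep(62, 1e5), 12)
  expect_true(all(r >= 1 & r <= 99))
  expect_true(all(r == floor(r)))
  expect_equal(mean(r), 62, tolerance = 0.15)
  expect_equal(sd(r), 12, tolerance = 0.15)
  expect_equal(sample_rewards(62.4, 0), 62L)
  expect_error(sample_rewards(50, 60), "beta")
})

test_that("calibrate_sampling_sd hits the 75% exceedance target", {
  # single round, normal-approximation oracle: sd ~ (m - 50) / z_0.75
  sd1 <- calibrate_sampling_sd(60)
  expect_equal(sd1, 10 / qnorm(0.75), tolerance = 0.06 * sd1)
  # Monte-Carlo validation of the calibrated pooled target
  set.seed(17)
  means <- c(56, 59, 63, 66)
  lens <- c(8, 12, 20, 24)
  s <- calibrate_sampling_sd(means, weights = lens)
  draws <- sample_rewards(rep(rep(means, lens), 2000), s)
  expect_equal(mean(draws > 50), 0.75, tolerance = 0.006)
  expect_error(calibrate_sampling_sd(c(50, 50)), "exceed 50")
})

test_that("effective variances separate sampling noise from drift", {
  ts <- test_taskset()
  for (cond in c("Ref", "S+")) {
    expect_equal(ts$genspec[[cond]]$v_d_eff, 0)
  }
  expect_gt(ts$genspec[["V+"]]$v_d_eff, 0)
  # sampling variance close to the squared rescaled reward SD
  expect_equal(ts$genspec[["Ref"]]$v_s_eff, (ts$sampling_sd / 100)^2,
               tolerance = 0.25)
  # V+ drift variance against a direct Monte-Carlo oracle of the generator:
  # variance of successive mean increments on the rescaled scale
  v <- ts$blocks[ts$blocks$condition == "V+", ]
  incr <- unlist(lapply(split(v$mean_1, v$block), diff)) / 100
  expect_equal(ts$genspec[["V+"]]$v_d_eff, var(incr))
})

test_that("difficulty matching equalizes greedy-KF accuracy between S+ and V+", {
  ts <- test_taskset()
  splus <- ts$blocks[ts$blocks$condition == "S+", ]
  # independent re-simulation of the matched S+ accuracy
  set.seed(18)
  acc <- optimal_accuracy(splus, ts$sampling_sd,
                          ts$genspec[["Ref"]]$v_s_eff, 0, n_sims = 4000)
  expect_equal(acc, ts$vplus_accuracy, tolerance = 0.015)
  # unreachable targets error out
  ref <- ts$blocks[ts$blocks$condition == "Ref", ]
  expect_error(
    match_splus_difficulty(ref, ts$sampling_sd, vplus_accuracy = 0.501,
                           v_s_eff = ts$genspec[["Ref"]]$v_s_eff,
                           n_sims = 400),
    "reached 50")
  expect_error(
    match_splus_difficulty(ref, ts$sampling_sd, vplus_accuracy = 0.999,
                           v_s_eff = ts$genspec[["Ref"]]$v_s_eff,
                           n_sims = 400),
    "exceeds")
})

test_that("every generated block passes the schedule invariants", {
  ts <- test_taskset()
  b <- ts$blocks
  expect_equal(b$mean_1 + b$mean_2, rep(100, nrow(b)))
  expect_true(all(b$reward_1 >= 1 & b$reward_1 <= 99))
  expect_true(all(b$reward_2 >= 1 & b$reward_2 <= 99))
  for (cond in c("Ref", "S+", "V+")) {
    for (blk in unique(b$block)) {
      sub <- b[b$condition == cond & b$block == blk, ]
      expect_equal(nrow(sub), 80)
      if (cond != "V+") {
        expect_equal(sort(rle(sub$round)$lengths), c(8, 12, 16, 20, 24))
      }
    }
  }
})

test_that("summary statistics are invariant to option relabeling", {
  ts <- test_taskset()
  ref <- ts$blocks[ts$blocks$condition == "Ref", ]
  sw <- swap_block_options(ref)
  g1 <- compute_effective_variances(ref)
  g2 <- compute_effective_variances(sw)
  expect_equal(g1$v_s_eff, g2$v_s_eff)
  expect_equal(g1$v_d_eff, g2$v_d_eff)
  set.seed(19)
  a1 <- optimal_accuracy(ref, ts$sampling_sd, g1$v_s_eff, 0, n_sims = 3000)
  set.seed(19)
  a2 <- optimal_accuracy(sw, ts$sampling_sd, g2$v_s_eff, 0, n_sims = 3000)
  expect_equal(a1, a2, tolerance = 0.02)
})
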