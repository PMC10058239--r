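# Agent-on-schedule simulation and the model-free behavioral summaries.

test_that("greedy noise-free agents are deterministic and exploit easy schedules", {
  b <- toy_blocks(n_rounds = 2, len = 20, mean_dev = 40, sd = 2)
  p <- agent_params(alpha = 0.5, zeta = 0, delta = 0, tau = 0)
  set.seed(21)
  s1 <- run_session(p, b)
  set.seed(21)
  s2 <- run_session(p, b)
  expect_identical(s1, s2)
  # accuracy approaches 1 after the first trial of each round
  late <- s1$correct[s1$trial %% 20 > 3]
  expect_gt(mean(late), 0.95)
})

test_that("infinite temperature gives chance accuracy and 50% switching", {
  b <- toy_blocks(n_rounds = 2, len = 40, mean_dev = 20, sd = 8)
  p <- agent_params(alpha = 0.5, zeta = 0, delta = 0, tau = 100)
  set.seed(22)
  sm <- lapply(1:80, function(i) summarize_session(run_session(p, b)))
  acc <- mean(vapply(sm, `[[`, numeric(1), "accuracy"))
  sw <- mean(vapply(sm, `[[`, numeric(1), "switch_rate"))
  expect_lt(abs(acc - 0.5), 0.025)
  expect_lt(abs(sw - 0.5), 0.025)
})

test_that("session summaries match a hand count", {
  ses <- data.frame(condition = "Ref", block = 1L, round = rep(1:2, each = 5),
                    trial = 1:10,
                    choice = c(1, 1, 2, 2, 2, 1, 2, 1, 2, 2),
                    reward = 60,
                    correct = c(TRUE, TRUE, FALSE, TRUE, TRUE,
                                FALSE, TRUE, TRUE, TRUE, FALSE),
                    switch = c(NA, FALSE, TRUE, FALSE, FALSE,
                               NA, TRUE, TRUE, TRUE, FALSE),
                    reversal_flag = FALSE)
  sm <- summarize_session(ses)
  expect_equal(sm$accuracy, 7 / 10)
  expect_equal(sm$switch_rate, 4 / 8)
  expect_error(summarize_session(ses[0, ]), "empty")
})

test_that("switch flags reset at round boundaries but not at reversals", {
  ts <- test_taskset()
  p <- agent_params(alpha = 0.4, zeta = 0, delta = 0, tau = 0.1)
  set.seed(23)
  ref <- run_session(p, ts$blocks[ts$blocks$condition == "Ref", ])
  key <- paste(ref$block, ref$round)
  first <- c(TRUE, key[-1] != key[-nrow(ref)])
  expect_true(all(is.na(ref$switch[first])))
  expect_true(all(!is.na(ref$switch[!first])))
  vp <- run_session(p, ts$blocks[ts$blocks$condition == "V+", ])
  expect_true(all(!is.na(vp$switch[vp$reversal_flag])))
})

test_that("aligned curve means reproduce overall accuracy on equal-length rounds", {
  b <- toy_blocks(n_rounds = 4, len = 10, mean_dev = 15, sd = 10)
  p <- agent_params(alpha = 0.4, zeta = 0.3, delta = 0.2, tau = 0.08)
  set.seed(24)
  ses <- run_session(p, b)
  ses$subject <- 1L
  cur <- aligned_curves(ses, align = "round_start")
  expect_equal(mean(cur$accuracy$mean), mean(ses$correct))
  expect_true(all(cur$accuracy$sem == 0))   # single subject
  expect_true(all(cur$accuracy$mean >= 0 & cur$accuracy$mean <= 1))
  expect_false(1 %in% cur$switch$position)  # undefined at round starts
})

test_that("optimal V+ accuracy dips after a reversal and recovers", {
  ts <- test_taskset()
  vp_blocks <- ts$blocks[ts$blocks$condition == "V+", ]
  opt <- make_optimal_agent(ts$genspec[["V+"]])
  set.seed(25)
  sessions <- do.call(rbind, lapply(1:60, function(i) {
    s <- run_session(opt, vp_blocks)
    s$subject <- i
    s
  }))
  cur <- aligned_curves(sessions, align = "reversal")$accuracy
  early <- cur$mean[cur$position == 1]
  late <- mean(cur$mean[cur$position %in% 5:8])
  expect_lt(early, late)
})

test_that("switch rate rises with temperature but not with learning noise", {
  ts <- test_taskset()
  blocks <- ts$blocks[ts$blocks$condition == "Ref", ]
  base <- agent_params(alpha = 0.4, zeta = 0.3, delta = 0.2, tau = 0.05)
  set.seed(26)
  sw_tau <- vapply(c(0.02, 0.08, 0.2, 0.5), function(tv) {
    p <- base; p$tau <- tv
    mean(vapply(1:15, function(i) {
      summarize_session(run_session(p, blocks))$switch_rate
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sw_tau) > 0))
  # a simulated cohort varying only zeta: switch rate does not increase
  set.seed(27)
  zgrid <- seq(0.05, 1.2, length.out = 12)
  sw_z <- vapply(zgrid, function(zv) {
    p <- base; p$zeta <- zv
    mean(vapply(1:15, function(i) {
      summarize_session(run_session(p, blocks))$switch_rate
    }, numeric(1)))
  }, numeric(1))
  expect_lte(cor(zgrid, sw_z, method = "spearman"), 0.3)
})
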