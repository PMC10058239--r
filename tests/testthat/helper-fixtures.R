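# Shared fixtures: a memoized small task set (difficulty matching at reduced
# simulation counts) and hand-built toy schedules for deterministic checks.

nb_fixture_env <- new.env(parent = emptyenv())

test_taskset <- function(seed = 101, match_n_sims = 2000) {
  key <- paste0("ts_", seed, "_", match_n_sims)
  if (!exists(key, envir = nb_fixture_env)) {
    set.seed(seed)
    assign(key, generate_task_set(match_n_sims = match_n_sims),
           envir = nb_fixture_env)
  }
  get(key, envir = nb_fixture_env)
}

# A static toy schedule with alternating round sides and known rewards.
toy_blocks <- function(n_rounds = 4, len = 10, mean_dev = 20, sd = 8,
                       condition = "Ref", block = 1L) {
  means <- rep(c(50 + mean_dev, 50 - mean_dev), length.out = n_rounds)
  mean_1 <- rep(means, each = len)
  data.frame(condition = condition, block = block,
             trial = seq_len(n_rounds * len),
             round = rep(seq_len(n_rounds), each = len),
             mean_1 = mean_1, mean_2 = 100 - mean_1,
             reward_1 = sample_rewards(mean_1, sd),
             reward_2 = sample_rewards(100 - mean_1, sd),
             reversal_flag = FALSE)
}

# Relabel the two options of a block schedule.
swap_block_options <- function(blocks) {
  out <- blocks
  out$mean_1 <- blocks$mean_2
  out$mean_2 <- blocks$mean_1
  out$reward_1 <- blocks$reward_2
  out$reward_2 <- blocks$reward_1
  out
}

# Relabel the options of a session record (choices flip; rewards stay).
swap_session_options <- function(session) {
  out <- session
  out$choice <- 3L - session$choice
  out
}
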