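# Running agents on task blocks and computing the model-free behavioral
# summaries: accuracy, switch rate, and accuracy/switch time courses aligned
# to round starts (Ref/S+) or block starts and reversals (V+).

#' Simulate a session of one agent on one condition's blocks
#'
#' Runs the full generative loop: on each trial the agent chooses by the
#' softmax policy on its current value estimates, observes the realized
#' reward of the chosen option, and updates its state. The learner is
#' reinitialized at the start of every round in the Ref/S+ conditions (new
#' option pairs) and at the start of every block in the V+ condition
#' (reversals are covert).
#'
#' @param params An `nb_params` object.
#' @param blocks Block data.frame for a single condition.
#' @return A session data.frame with per-trial columns `condition`, `block`,
#'   `round`, `trial`, `choice`, `reward` (points, chosen option), `correct`
#'   (chosen option has the higher generative mean), `switch` (choice differs
#'   from the previous trial; `NA` on the first trial after each
#'   reinitialization), and `reversal_flag`.
#' @export
run_session <- function(params, blocks) {
  stopifnot(inherits(params, "nb_params"), length(unique(blocks$condition)) == 1)
  reinit <- reinit_flags(blocks)
  choice <- cpp_simulate_choices(blocks$reward_1, blocks$reward_2, reinit,
                                 params$zeta, params$delta, params$tau,
                                 params$v_s, params$v_d, params$v0)
  reward <- ifelse(choice == 1, blocks$reward_1, blocks$reward_2)
  best <- ifelse(blocks$mean_1 > blocks$mean_2, 1L, 2L)
  sw <- c(NA, choice[-1] != choice[-length(choice)])
  sw[reinit] <- NA
  data.frame(condition = blocks$condition, block = blocks$block,
             round = blocks$round, trial = blocks$trial,
             choice = choice, reward = reward,
             correct = choice == best, switch = sw,
             reversal_flag = blocks$reversal_flag)
}

#' Accuracy and switch rate of a session
#'
#' @param session A session data.frame from [run_session()].
#' @return A list with `accuracy` (mean of the correct flags) and
#'   `switch_rate` (mean of the defined switch flags).
#' @export
summarize_session <- function(session) {
  if (nrow(session) == 0) stop("summarize_session: empty session")
  list(accuracy = mean(session$correct),
       switch_rate = mean(session$switch, na.rm = TRUE))
}

# Alignment positions for one session: trials since the last alignment point
# (round start, or block start + reversals).
alignment_positions <- function(session, align) {
  anchor <- switch(align,
    round_start = {
      key <- paste(session$block, session$round)
      c(TRUE, key[-1] != key[-nrow(session)])
    },
    reversal = {
      blk <- c(TRUE, session$block[-1] != session$block[-nrow(session)])
      blk | session$reversal_flag
    },
    stop("align must be 'round_start' or 'reversal'")
  )
  seg <- cumsum(anchor)
  stats::ave(seq_len(nrow(session)), seg, FUN = seq_along)
}

#' Aligned accuracy and switch-rate time courses
#'
#' Averages the per-trial correct and switch flags by position relative to
#' the start of each round (`align = "round_start"`, for Ref/S+) or relative
#' to each block start and reversal (`align = "reversal"`, for V+), first
#' within subject, then across subjects (mean and SEM with an `n - 1`
#' denominator; the SEM of a single subject is reported as 0).
#'
#' @param sessions A session data.frame with a `subject` column (a single
#'   session is treated as one subject).
#' @param align `"round_start"` or `"reversal"`.
#' @return A list of two data.frames (`accuracy`, `switch`) with columns
#'   `position`, `mean`, `sem`, `n`.
#' @export
aligned_curves <- function(sessions, align = c("round_start", "reversal")) {
  align <- match.arg(align)
  if (nrow(sessions) == 0) stop("aligned_curves: no sessions")
  if (is.null(sessions$subject)) sessions$subject <- 1L
  per_subject <- lapply(split(sessions, sessions$subject), function(s) {
    pos <- alignment_positions(s, align)
    acc <- tapply(s$correct, pos, mean)
    swd <- !is.na(s$switch)
    sw <- tapply(ifelse(swd, s$switch, NA), pos, mean, na.rm = TRUE)
    data.frame(position = as.integer(names(acc)), accuracy = as.numeric(acc),
               switch = as.numeric(sw))
  })
  long <- do.call(rbind, per_subject)
  curve_of <- function(col) {
    m <- tapply(long[[col]], long$position, mean, na.rm = TRUE)
    s <- tapply(long[[col]], long$position, function(v) {
      v <- v[!is.na(v)]
      if (length(v) <= 1) 0 else sd(v) / sqrt(length(v))
    })
    n <- tapply(!is.na(long[[col]]), long$position, sum)
    keep <- n > 0
    data.frame(position = as.integer(names(m))[keep],
               mean = as.numeric(m)[keep], sem = as.numeric(s)[keep],
               n = as.integer(n)[keep])
  }
  list(accuracy = curve_of("accuracy"), switch = curve_of("switch"))
}
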