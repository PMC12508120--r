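# Shared fixtures built in code.

# Minimal trial table from explicit choice/reward sequences; timestamps laid
# out with the default task timing so alignment code can consume it.
make_trials <- function(chosen, rewarded, block = NULL, better = NULL,
                        iti = 10, reward_delay = 1, timeout = 5) {
  n <- length(chosen)
  if (is.null(block)) block <- rep(1L, n)
  if (is.null(better)) better <- rep("L", n)
  df <- data.frame(
    index = seq_len(n), block = block, better_side = better,
    chosen_side = chosen, rewarded = as.integer(rewarded),
    better_chosen = as.integer(chosen == better),
    t_init_cue = NA_real_, t_init = NA_real_, t_choice = NA_real_,
    t_reward_cue = NA_real_, t_retrieval = NA_real_,
    init_latency = 1, choice_latency = 1.5, reward_latency = NA_real_,
    stringsAsFactors = FALSE)
  t_now <- 0
  for (i in seq_len(n)) {
    df$t_init_cue[i] <- t_now
    df$t_init[i] <- t_now + 1
    df$t_choice[i] <- t_now + 2.5
    if (df$rewarded[i] == 1) {
      df$t_reward_cue[i] <- df$t_choice[i] + reward_delay
      df$t_retrieval[i] <- df$t_reward_cue[i] + 1
      df$reward_latency[i] <- 1
      t_end <- df$t_retrieval[i]
    } else {
      t_end <- df$t_choice[i] + timeout
    }
    t_now <- t_end + iti
  }
  class(df) <- c("trial_table", "data.frame")
  df
}

# A short schedule-3 session with all four side-by-outcome conditions
# populated, plus planted cells.
small_session <- function(seed = 1, block_length = 30,
                          agent = agent_params("wsls",
                                               p_stay_after_win = 0.7,
                                               p_shift_after_loss = 0.7)) {
  simulate_session(task_config(3, block_length = block_length), agent, seed)
}

binomial_ci_half <- function(n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(0.5 - z * sqrt(0.25 / n), 0.5 + z * sqrt(0.25 / n))
}
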