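#' Task configuration for a probabilistic reversal session
#'
#' Describes one session of the three-block probabilistic reversal task:
#' reward-probability ratios per block, which side is "better" in each block
#' (alternating at every block boundary), and the trial timing constants.
#'
#' The three standard schedules increase in outcome uncertainty:
#' \describe{
#'   \item{Schedule 1}{100:0 for blocks 1--2, 90:10 for block 3}
#'   \item{Schedule 2}{90:10 for blocks 1--2, 80:20 for block 3}
#'   \item{Schedule 3}{80:20 for blocks 1--2, 70:30 for block 3}
#' }
#'
#' @param schedule Integer 1--3 selecting a standard schedule. Ignored if
#'   `blocks` is supplied.
#' @param blocks Optional data.frame with columns `p_better`, `p_worse`
#'   (percent, `p_better > p_worse`, both in \[0, 100\]) and `better_side`
#'   (`"L"`/`"R"`, must alternate). Exactly 3 rows.
#' @param block_length Committed trials per block (default 75, so 225/session).
#' @param reward_delay Seconds from choice nosepoke to reward cue (default 1).
#' @param iti Inter-trial interval, seconds (default 10).
#' @param timeout Timeout after unrewarded trials, seconds (default 5).
#' @param init_deadline,choice_deadline Response deadlines in seconds
#'   (defaults 40 and 60).
#' @param first_better_side Better side of block 1 (`"L"` or `"R"`).
#' @return A `task_config` list.
#' @export
task_config <- function(schedule = 1L, blocks = NULL, block_length = 75L,
                        reward_delay = 1, iti = 10, timeout = 5,
                        init_deadline = 40, choice_deadline = 60,
                        first_better_side = "L") {
  if (is.null(blocks)) {
    ratios <- switch(as.character(schedule),
      "1" = list(c(100, 0), c(100, 0), c(90, 10)),
      "2" = list(c(90, 10), c(90, 10), c(80, 20)),
      "3" = list(c(80, 20), c(80, 20), c(70, 30)),
      stop_prl("schedule must be 1, 2 or 3", "prl_config_error"))
    sides <- if (first_better_side == "L") c("L", "R", "L") else c("R", "L", "R")
    blocks <- data.frame(
      p_better = vapply(ratios, `[`, numeric(1), 1),
      p_worse = vapply(ratios, `[`, numeric(1), 2),
      better_side = sides, stringsAsFactors = FALSE)
  }
  if (nrow(blocks) != 3L)
    stop_prl("a session must have exactly 3 blocks", "prl_config_error")
  if (!all(blocks$better_side %in% c("L", "R")))
    stop_prl("better_side must be 'L' or 'R'", "prl_config_error")
  if (any(blocks$better_side[-1] == blocks$better_side[-3]))
    stop_prl("better_side must alternate between consecutive blocks",
             "prl_config_error")
  if (any(blocks$p_better < 0 | blocks$p_better > 100 |
          blocks$p_worse < 0 | blocks$p_worse > 100))
    stop_prl("reward probabilities must be percentages in [0, 100]",
             "prl_config_error")
  if (any(blocks$p_better <= blocks$p_worse))
    stop_prl("p_better must exceed p_worse in every block", "prl_config_error")
  if (block_length < 1)
    stop_prl("block_length must be a positive integer", "prl_config_error")
  structure(list(
    schedule = as.integer(schedule), blocks = blocks,
    block_length = as.integer(block_length), reward_delay = reward_delay,
    iti = iti, timeout = timeout, init_deadline = init_deadline,
    choice_deadline = choice_deadline), class = "task_config")
}

#' Choice-agent parameters
#'
#' Parametric choice processes used by the task simulator. Three kinds are
#' provided: a win-stay/lose-shift agent (`"wsls"`), a Q-learning agent with
#' a softmax (logistic) choice rule (`"q_learning"`), and a deterministic
#' `"forced_better"` agent that always selects the current block's better
#' side (useful for probing the programmed reward schedule).
#'
#' Response latencies (initiation, choice, reward retrieval) are drawn from
#' log-normal distributions: strictly positive and right-skewed like real
#' operant latencies.
#'
#' @param kind `"wsls"`, `"q_learning"` or `"forced_better"`.
#' @param p_stay_after_win,p_shift_after_loss WSLS probabilities in \[0, 1\].
#' @param alpha Q-learning rate in \[0, 1\].
#' @param beta Inverse temperature, >= 0.
#' @param initial_value Named numeric `c(L = , R = )` of initial side values.
#' @param latency Named list of log-normal location/scale per latency type,
#'   as produced by [latency_model()].
#' @return An `agent_params` list.
#' @export
agent_params <- function(kind = c("wsls", "q_learning", "forced_better"),
                         p_stay_after_win = 0.8, p_shift_after_loss = 0.8,
                         alpha = 0.3, beta = 5,
                         initial_value = c(L = 0.5, R = 0.5),
                         latency = latency_model()) {
  kind <- match.arg(kind)
  if (p_stay_after_win < 0 || p_stay_after_win > 1 ||
      p_shift_after_loss < 0 || p_shift_after_loss > 1)
    stop_prl("wsls probabilities must lie in [0, 1]", "prl_config_error")
  if (alpha < 0 || alpha > 1)
    stop_prl("learning rate alpha must lie in [0, 1]", "prl_config_error")
  if (beta < 0)
    stop_prl("inverse temperature beta must be >= 0", "prl_config_error")
  structure(list(kind = kind, p_stay_after_win = p_stay_after_win,
                 p_shift_after_loss = p_shift_after_loss, alpha = alpha,
                 beta = beta, initial_value = initial_value,
                 latency = latency), class = "agent_params")
}

#' Log-normal latency model parameters
#'
#' @param init_meanlog,init_sdlog Initiation latency location/scale.
#' @param choice_meanlog,choice_sdlog Choice latency location/scale.
#' @param reward_meanlog,reward_sdlog Reward-retrieval latency location/scale.
#' @return Named list of log-normal parameters (seconds scale).
#' @export
latency_model <- function(init_meanlog = log(2), init_sdlog = 0.5,
                          choice_meanlog = log(1.5), choice_sdlog = 0.5,
                          reward_meanlog = log(1), reward_sdlog = 0.4) {
  list(init_meanlog = init_meanlog, init_sdlog = init_sdlog,
       choice_meanlog = choice_meanlog, choice_sdlog = choice_sdlog,
       reward_meanlog = reward_meanlog, reward_sdlog = reward_sdlog)
}

#' Initialize agent state
#'
#' @param agent An [agent_params()] object.
#' @return Opaque state list passed to [agent_step()].
#' @export
agent_init <- function(agent) {
  list(V = agent$initial_value)
}

#' Advance the choice agent by one trial
#'
#' Consumes the previous trial's choice and reward and returns the next
#' choice. For the WSLS agent: after a win, the previous side is repeated
#' with probability `p_stay_after_win`; after a loss, the agent switches
#' with probability `p_shift_after_loss`; the first trial is uniform. For
#' the Q-learning agent the chosen side's value is updated by
#' `V <- V + alpha * (r - V)` and the next choice is drawn from a logistic
#' rule with inverse temperature `beta`. Draws come from the current RNG
#' stream; callers wanting reproducibility seed it themselves (the session
#' simulator does).
#'
#' @param agent An [agent_params()] object.
#' @param state State list from [agent_init()] or a previous step.
#' @param last_choice `"L"`, `"R"` or `NULL` on the first trial.
#' @param last_reward 0/1 or `NULL` on the first trial.
#' @param better_side Current better side (used by the forced agent only).
#' @return List with elements `choice` (`"L"`/`"R"`) and updated `state`.
#' @export
agent_step <- function(agent, state, last_choice = NULL, last_reward = NULL,
                       better_side = NULL) {
  if (agent$kind == "forced_better") {
    if (is.null(better_side))
      stop_prl("forced_better agent needs better_side", "prl_config_error")
    return(list(choice = better_side, state = state))
  }
  if (agent$kind == "wsls") {
    if (is.null(last_choice)) {
      choice <- sample(c("L", "R"), 1L)
    } else if (isTRUE(last_reward == 1)) {
      stay <- stats::runif(1) < agent$p_stay_after_win
      choice <- if (stay) last_choice else setdiff(c("L", "R"), last_choice)
    } else {
      shift <- stats::runif(1) < agent$p_shift_after_loss
      choice <- if (shift) setdiff(c("L", "R"), last_choice) else last_choice
    }
    return(list(choice = choice, state = state))
  }
  # q_learning
  if (!is.null(last_choice)) {
    state$V[last_choice] <- state$V[last_choice] +
      agent$alpha * (last_reward - state$V[last_choice])
  }
  p_left <- 1 / (1 + exp(-agent$beta * (state$V["L"] - state$V["R"])))
  choice <- if (stats::runif(1) < p_left) "L" else "R"
  list(choice = choice, state = state)
}

#' Simulate one session of the probabilistic reversal task
#'
#' Generates the committed-trial event table for a full session: three
#' blocks of `block_length` trials with the better side reversing at each
#' block boundary, per-trial reward drawn with the chosen side's programmed
#' probability, and event timestamps laid out with the task's timing
#' constants (reward cue `reward_delay` s after choice on rewarded trials, a
#' `timeout` after unrewarded trials, and an `iti` between trials).
#' Omissions are not simulated; every generated trial is a committed trial.
#'
#' @param config A [task_config()].
#' @param agent An [agent_params()].
#' @param seed Integer seed; identical `(config, agent, seed)` give
#'   identical tables.
#' @return A `trial_table` data.frame, one row per committed trial, with
#'   columns `index`, `block`, `better_side`, `chosen_side`, `rewarded`,
#'   `better_chosen`, `t_init_cue`, `t_init`, `t_choice`, `t_reward_cue`,
#'   `t_retrieval` (the last two `NA` on unrewarded trials), `init_latency`,
#'   `choice_latency`, `reward_latency` (seconds).
#' @export
simulate_session <- function(config, agent, seed) {
  stopifnot(inherits(config, "task_config"), inherits(agent, "agent_params"))
  with_seed(seed, {
    n <- 3L * config$block_length
    lat <- agent$latency
    out <- data.frame(
      index = seq_len(n), block = rep(1:3, each = config$block_length),
      better_side = rep(config$blocks$better_side, each = config$block_length),
      chosen_side = NA_character_, rewarded = NA_integer_,
      better_chosen = NA_integer_, t_init_cue = NA_real_, t_init = NA_real_,
      t_choice = NA_real_, t_reward_cue = NA_real_, t_retrieval = NA_real_,
      init_latency = NA_real_, choice_latency = NA_real_,
      reward_latency = NA_real_, stringsAsFactors = FALSE)
    state <- agent_init(agent)
    t_now <- 0
    last_choice <- NULL
    last_reward <- NULL
    for (i in seq_len(n)) {
      b <- out$block[i]
      step <- agent_step(agent, state, last_choice, last_reward,
                         better_side = out$better_side[i])
      state <- step$state
      choice <- step$choice
      p_reward <- if (choice == out$better_side[i])
        config$blocks$p_better[b] / 100 else config$blocks$p_worse[b] / 100
      rewarded <- as.integer(stats::runif(1) < p_reward)
      init_lat <- rlnorm_trunc(1, lat$init_meanlog, lat$init_sdlog,
                               config$init_deadline)
      choice_lat <- rlnorm_trunc(1, lat$choice_meanlog, lat$choice_sdlog,
                                 config$choice_deadline)
      out$t_init_cue[i] <- t_now
      out$t_init[i] <- t_now + init_lat
      out$t_choice[i] <- out$t_init[i] + choice_lat
      out$init_latency[i] <- init_lat
      out$choice_latency[i] <- choice_lat
      out$chosen_side[i] <- choice
      out$rewarded[i] <- rewarded
      out$better_chosen[i] <- as.integer(choice == out$better_side[i])
      if (rewarded == 1L) {
        reward_lat <- stats::rlnorm(1, lat$reward_meanlog, lat$reward_sdlog)
        out$t_reward_cue[i] <- out$t_choice[i] + config$reward_delay
        out$t_retrieval[i] <- out$t_reward_cue[i] + reward_lat
        out$reward_latency[i] <- reward_lat
        trial_end <- out$t_retrieval[i]
      } else {
        trial_end <- out$t_choice[i] + config$timeout
      }
      t_now <- trial_end + config$iti
      last_choice <- choice
      last_reward <- rewarded
    }
    attr(out, "config") <- config
    class(out) <- c("trial_table", "data.frame")
    out
  })
}

#' @export
print.trial_table <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Trial table: %d committed trials in %d blocks\n",
              nrow(x), length(unique(x$block))))
  if (!is.null(cfg))
    cat(sprintf("  schedule %d, block ratios %s\n", cfg$schedule,
                paste(sprintf("%g:%g", cfg$blocks$p_better,
                              cfg$blocks$p_worse), collapse = ", ")))
  cat(sprintf("  p(Better) = %.3f, rewarded = %.3f\n",
              mean(x$better_chosen), mean(x$rewarded)))
  invisible(x)
}
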