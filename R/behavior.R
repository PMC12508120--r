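#' Win-stay proportion
#'
#' Proportion of all trials with a predecessor on which the animal had been
#' rewarded on the previous trial and repeated that choice. The default
#' denominator is `N - 1` (all trials with a predecessor), taking
#' "proportion of all trials" literally; `conditional = TRUE` instead
#' divides by the number of post-win trials.
#'
#' @param trials A `trial_table` (>= 2 trials).
#' @param conditional Use post-win trials as the denominator.
#' @return Proportion in \[0, 1\].
#' @export
win_stay <- function(trials, conditional = FALSE) {
  n <- nrow(trials)
  if (n < 2) stop_prl("need at least 2 trials", "prl_precondition_error")
  prev_win <- trials$rewarded[-n] == 1
  stay <- trials$chosen_side[-1] == trials$chosen_side[-n]
  num <- sum(prev_win & stay)
  den <- if (conditional) sum(prev_win) else n - 1
  if (den == 0) return(0)
  num / den
}

#' Lose-shift proportion
#'
#' Mirror of [win_stay()]: trials whose predecessor was unrewarded and whose
#' choice switched sides.
#'
#' @inheritParams win_stay
#' @return Proportion in \[0, 1\].
#' @export
lose_shift <- function(trials, conditional = FALSE) {
  n <- nrow(trials)
  if (n < 2) stop_prl("need at least 2 trials", "prl_precondition_error")
  prev_loss <- trials$rewarded[-n] == 0
  shift <- trials$chosen_side[-1] != trials$chosen_side[-n]
  num <- sum(prev_loss & shift)
  den <- if (conditional) sum(prev_loss) else n - 1
  if (den == 0) return(0)
  num / den
}

#' Perseveration index: mean trials to change choice after a loss
#'
#' For every unrewarded trial that starts a loss run on a side (i.e. is not
#' preceded by an unrewarded trial on the same side), counts the trials
#' until the chosen side changes. Runs unresolved at session end are
#' censored at the remaining trial count (configurable); a run starting on
#' the final trial has no following trial and is excluded.
#'
#' @param trials A `trial_table`.
#' @param censor Keep unresolved runs at their censored count (default);
#'   `FALSE` drops them.
#' @return Mean trials-to-shift (>= 1).
#' @export
perseveration_index <- function(trials, censor = TRUE) {
  n <- nrow(trials)
  ch <- trials$chosen_side
  rw <- trials$rewarded
  counts <- numeric(0)
  for (t in seq_len(n)) {
    if (rw[t] != 0) next
    if (t > 1 && rw[t - 1] == 0 && ch[t - 1] == ch[t]) next  # run continues
    if (t == n) next  # no following trial
    shift_at <- which(ch[(t + 1):n] != ch[t])
    if (length(shift_at) > 0) {
      counts <- c(counts, shift_at[1])
    } else if (censor) {
      counts <- c(counts, n - t)
    }
  }
  if (length(counts) == 0)
    stop_prl("perseveration index not computable: no qualifying loss events",
             "prl_not_computable")
  mean(counts)
}

#' Flexibility index
#'
#' Average of the pairwise block means of the better-choice indicator:
#' `mean( mean(m1, m2), mean(m2, m3) )` where `m_b` is the mean of the
#' better-chosen indicator over block `b`. Quantifies adaptation across the
#' two reversals; 1 for an animal that always chooses the better option.
#'
#' @param trials A `trial_table` with 3 complete blocks.
#' @return Scalar in \[0, 1\].
#' @export
flexibility_index <- function(trials) {
  if (!setequal(unique(trials$block), 1:3))
    stop_prl("flexibility index requires 3 blocks", "prl_precondition_error")
  m <- vapply(1:3, function(b) mean(trials$better_chosen[trials$block == b]),
              numeric(1))
  mean(c(mean(m[1:2]), mean(m[2:3])))
}

#' Moving win-stay / lose-shift traces
#'
#' Builds the per-trial win-stay and lose-shift indicator vectors (trial 1 is
#' 0: no predecessor) and smooths each with a centered moving mean whose
#' windows shrink at the session edges (the nominal span for window `w` at
#' trial `t` is `t - floor((w-1)/2) .. t + floor(w/2)`, clipped to the
#' session).
#'
#' @param trials A `trial_table`.
#' @param window Window width in trials (>= 1; default 10).
#' @return List with per-trial vectors `moving_ws`, `moving_ls` and the raw
#'   indicators `ws_indicator`, `ls_indicator`.
#' @export
moving_strategy <- function(trials, window = 10L) {
  if (window < 1) stop_prl("window must be >= 1", "prl_config_error")
  n <- nrow(trials)
  ws <- ls <- numeric(n)
  if (n >= 2) {
    prev_win <- trials$rewarded[-n] == 1
    stay <- trials$chosen_side[-1] == trials$chosen_side[-n]
    ws[-1] <- as.numeric(prev_win & stay)
    ls[-1] <- as.numeric(!prev_win & !stay)
  }
  movmean <- function(x, w) {
    lo_off <- floor((w - 1) / 2)
    hi_off <- floor(w / 2)
    vapply(seq_along(x), function(t) {
      mean(x[max(1, t - lo_off):min(length(x), t + hi_off)])
    }, numeric(1))
  }
  list(moving_ws = movmean(ws, window), moving_ls = movmean(ls, window),
       ws_indicator = ws, ls_indicator = ls)
}

#' Session latency medians
#'
#' Medians of the initiation, choice and reward-retrieval latencies; the
#' reward median is taken over rewarded trials only and is `NA` when the
#' session has none.
#'
#' @param trials A `trial_table`.
#' @return Named list `median_init_latency`, `median_choice_latency`,
#'   `median_reward_latency` (seconds).
#' @export
latency_summaries <- function(trials) {
  list(median_init_latency = stats::median(trials$init_latency, na.rm = TRUE),
       median_choice_latency = stats::median(trials$choice_latency, na.rm = TRUE),
       median_reward_latency =
         if (any(trials$rewarded == 1))
           stats::median(trials$reward_latency[trials$rewarded == 1],
                         na.rm = TRUE)
         else NA_real_)
}

#' All behavioural measures for one session
#'
#' @param trials A `trial_table`.
#' @param window Moving-average window for the strategy traces.
#' @return A `behavior_summary` list: `p_better` (session mean),
#'   `p_better_trialwise`, `win_stay`, `lose_shift`, `perseveration_index`
#'   (`NA` if not computable), `flexibility_index`, latency medians, and the
#'   moving strategy traces.
#' @export
behavior_summary <- function(trials, window = 10L) {
  mv <- moving_strategy(trials, window)
  pi_val <- tryCatch(perseveration_index(trials),
                     prl_not_computable = function(e) NA_real_)
  fi <- tryCatch(flexibility_index(trials),
                 prl_precondition_error = function(e) NA_real_)
  lat <- latency_summaries(trials)
  structure(c(list(
    p_better = mean(trials$better_chosen),
    p_better_trialwise = trials$better_chosen,
    win_stay = win_stay(trials), lose_shift = lose_shift(trials),
    perseveration_index = pi_val, flexibility_index = fi),
    lat,
    list(moving_ws = mv$moving_ws, moving_ls = mv$moving_ls)),
    class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("Session behaviour summary\n")
  cat(sprintf("  p(Better) %.3f | WinStay %.3f | LoseShift %.3f\n",
              x$p_better, x$win_stay, x$lose_shift))
  cat(sprintf("  Perseveration %.2f | Flexibility %.3f\n",
              x$perseveration_index, x$flexibility_index))
  cat(sprintf("  latency medians (s): init %.2f, choice %.2f, reward %.2f\n",
              x$median_init_latency, x$median_choice_latency,
              x$median_reward_latency))
  invisible(x)
}
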