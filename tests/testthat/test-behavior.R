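test_that("win-stay and lose-shift match hand-enumerated sequences", {
  # (choice, reward): (L,1),(L,0),(R,0),(R,1),(R,1),(L,0)
  tt <- make_trials(c("L", "L", "R", "R", "R", "L"), c(1, 0, 0, 1, 1, 0))
  expect_equal(win_stay(tt), 2 / 5)
  expect_equal(lose_shift(tt), 1 / 5)
  # forced extremes
  all_win_stay <- make_trials(rep("L", 6), rep(1, 6))
  expect_equal(win_stay(all_win_stay), 1.0)
  no_wins <- make_trials(rep(c("L", "R"), 3), rep(0, 6))
  expect_equal(win_stay(no_wins), 0.0)
  expect_equal(lose_shift(no_wins), 1.0)  # perfect loss-switcher
  all_wins <- make_trials(rep("L", 6), rep(1, 6))
  expect_equal(lose_shift(all_wins), 0.0)
  expect_error(win_stay(make_trials("L", 1)), class = "prl_precondition_error")
  # conditional denominators
  expect_equal(win_stay(tt, conditional = TRUE), 2 / 3)
  expect_equal(lose_shift(tt, conditional = TRUE), 1 / 2)
})

test_that("perseveration index counts trials to shift after a first loss", {
  # immediate shifter: every loss is followed by a side change
  tt1 <- make_trials(c("L", "R", "L", "R", "L"), c(0, 0, 0, 0, 1))
  expect_equal(perseveration_index(tt1), 1.0)
  # single loss run resolved after 3 trials
  tt2 <- make_trials(c("L", "L", "L", "R", "R"), c(0, 0, 0, 1, 1))
  expect_equal(perseveration_index(tt2), 3.0)
  # all-rewarded session is not computable
  tt3 <- make_trials(rep("L", 5), rep(1, 5))
  expect_error(perseveration_index(tt3), class = "prl_not_computable")
  # unresolved run censored at the remaining trial count
  tt4 <- make_trials(c("L", "L", "L"), c(0, 0, 0))
  expect_equal(perseveration_index(tt4, censor = TRUE), 2.0)
  expect_error(perseveration_index(tt4, censor = FALSE),
               class = "prl_not_computable")
})

test_that("flexibility index averages the pairwise block means of better choices", {
  # block means (0.8, 0.6, 0.4) -> mean(0.7, 0.5) = 0.6
  block <- rep(1:3, each = 5)
  better <- rep("L", 15)
  chosen <- c("L", "L", "L", "L", "R",   # 0.8
              "L", "L", "L", "R", "R",   # 0.6
              "L", "L", "R", "R", "R")   # 0.4
  tt <- make_trials(chosen, rep(1, 15), block = block, better = better)
  expect_equal(flexibility_index(tt), 0.6)
  # always-better agent scores 1
  tt_b <- simulate_session(task_config(1), agent_params("forced_better"), 1)
  expect_equal(flexibility_index(tt_b), 1.0)
  expect_error(flexibility_index(make_trials(c("L", "R"), c(1, 0))),
               class = "prl_precondition_error")
})

test_that("a uniform agent has flexibility near one half", {
  # uniform choice = wsls with stay/shift probabilities of 0.5
  ag <- agent_params("wsls", p_stay_after_win = 0.5, p_shift_after_loss = 0.5)
  fis <- vapply(1:45, function(s)
    flexibility_index(simulate_session(task_config(3), ag, s)), numeric(1))
  n <- 45 * 225
  expect_lt(abs(mean(fis) - 0.5), 2.58 * sqrt(0.25 / n) + 0.02)
})

test_that("moving strategy traces equal a brute-force sliding mean", {
  chosen <- c("L", "L", "R", "R", "R", "L", "L", "R", "L", "L")
  reward <- c(1, 1, 0, 1, 0, 0, 1, 1, 0, 0)
  tt <- make_trials(chosen, reward)
  mv <- moving_strategy(tt, window = 5)
  # oracle: indicators then direct enumeration of shrinking centered windows
  n <- 10
  ws_ind <- c(0, as.numeric(reward[-n] == 1 & chosen[-1] == chosen[-n]))
  ls_ind <- c(0, as.numeric(reward[-n] == 0 & chosen[-1] != chosen[-n]))
  brute <- function(x, w) vapply(seq_len(n), function(t)
    mean(x[max(1, t - floor((w - 1) / 2)):min(n, t + floor(w / 2))]),
    numeric(1))
  expect_equal(mv$moving_ws, brute(ws_ind, 5))
  expect_equal(mv$moving_ls, brute(ls_ind, 5))
  # a window covering the whole session reproduces the session proportion
  mv_full <- moving_strategy(tt, window = 2 * n - 1)
  expect_equal(mv_full$moving_ws[ceiling(n / 2)], mean(ws_ind))
  # constant indicator -> constant trace
  tt_c <- make_trials(rep("L", 8), rep(1, 8))
  expect_equal(unique(moving_strategy(tt_c, 3)$moving_ws[3:8]), 1)
  expect_error(moving_strategy(tt, window = 0), class = "prl_config_error")
})

test_that("latency medians follow their definitions", {
  tt <- make_trials(rep("L", 3), c(1, 1, 1))
  tt$init_latency <- c(1, 2, 9)
  expect_equal(latency_summaries(tt)$median_init_latency, 2)
  tt_u <- make_trials(rep("L", 4), rep(0, 4))
  expect_true(is.na(latency_summaries(tt_u)$median_reward_latency))
  # analytic oracle: median of log-normal(0, 1) is exp(0) = 1
  ag <- agent_params("wsls",
                     latency = latency_model(reward_meanlog = 0,
                                             reward_sdlog = 1))
  lats <- unlist(lapply(1:30, function(s) {
    tt <- simulate_session(task_config(1), ag, s)
    tt$reward_latency[tt$rewarded == 1]
  }))
  expect_gt(length(lats), 2000)
  expect_lt(abs(median(lats) - 1), 0.06)
})

test_that("measured win-stay matches an independent process-level oracle", {
  # oracle: direct simulation of the wsls process in a stationary 80:20
  # environment, written without the package's simulator
  oracle_ws <- function(q_stay, q_shift, n = 60000, seed = 99) {
    set.seed(seed)
    ch <- integer(n); rw <- integer(n)
    ch[1] <- rbinom(1, 1, 0.5)
    rw[1] <- rbinom(1, 1, ifelse(ch[1] == 0, 0.8, 0.2))
    for (t in 2:n) {
      ch[t] <- if (rw[t - 1] == 1) {
        if (runif(1) < q_stay) ch[t - 1] else 1 - ch[t - 1]
      } else {
        if (runif(1) < q_shift) 1 - ch[t - 1] else ch[t - 1]
      }
      rw[t] <- rbinom(1, 1, ifelse(ch[t] == 0, 0.8, 0.2))
    }
    mean(rw[-n] == 1 & ch[-1] == ch[-n])
  }
  cfg <- task_config(blocks = data.frame(p_better = c(80, 80, 80),
                                         p_worse = c(20, 20, 20),
                                         better_side = c("L", "R", "L")),
                     block_length = 75)
  for (pars in list(c(0.9, 0.5), c(0.6, 0.8), c(0.95, 0.2))) {
    ag <- agent_params("wsls", p_stay_after_win = pars[1],
                       p_shift_after_loss = pars[2])
    ws <- mean(vapply(1:40, function(s)
      win_stay(simulate_session(cfg, ag, s)), numeric(1)))
    expect_lt(abs(ws - oracle_ws(pars[1], pars[2])), 0.025)
  }
})

test_that("behavior_summary bundles all session measures", {
  tt <- small_session(33, block_length = 75)
  bs <- behavior_summary(tt)
  expect_equal(bs$p_better, mean(tt$better_chosen))
  expect_equal(bs$p_better_trialwise, tt$better_chosen)
  expect_true(bs$win_stay >= 0 && bs$win_stay <= 1)
  expect_true(bs$lose_shift >= 0 && bs$lose_shift <= 1)
  expect_true(bs$flexibility_index >= 0 && bs$flexibility_index <= 1)
  expect_gte(bs$perseveration_index, 1)
  expect_length(bs$moving_ws, nrow(tt))
})
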