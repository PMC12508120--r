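# Build an epoch tensor directly from an activity array (cells x bins x
# trials) so decoder tests can plant exact geometry.
tensor_from_array <- function(values, anchor_pos = 21L, fps = 20) {
  n_bins <- dim(values)[2]
  structure(list(values = values,
                 bin_centers = seq_len(n_bins) - anchor_pos / fps,
                 anchor_pos = anchor_pos, fps = fps,
                 epoch = epoch_definition("choice"),
                 trial_index_map = seq_len(dim(values)[3]),
                 bin_width = 6L, bin_stride = 2L),
            class = "epoch_tensor")
}

balanced_labels <- function(per_cond = 10) {
  tt <- data.frame(
    chosen_side = rep(c("L", "L", "R", "R"), per_cond),
    rewarded = rep(c(1, 0, 1, 0), per_cond))
  trial_labels(tt)
}

test_that("balanced training sets take m = min available per condition and exclude the test trial", {
  labels <- balanced_labels(10)  # 10 per condition, trial 1 is LW
  idx <- balanced_train_indices(labels, test_trial = 1, seed = 3)
  expect_length(idx, 36)  # 9 per condition
  expect_false(1 %in% idx)
  expect_equal(as.integer(table(labels$condition[idx])), rep(9L, 4))
  # fresh draw per seed, sampling without replacement
  idx2 <- balanced_train_indices(labels, test_trial = 1, seed = 4)
  expect_false(identical(idx, idx2))
  expect_equal(anyDuplicated(idx), 0)
  expect_identical(balanced_train_indices(labels, 1, seed = 3), idx)
})

test_that("an empty condition makes the session not decodable", {
  tt <- data.frame(chosen_side = c(rep("L", 5), rep("R", 13)),
                   rewarded = c(rep(1, 5), rep(1, 7), rep(0, 6)))
  labels <- trial_labels(tt)  # LU empty
  expect_error(balanced_train_indices(labels, 1, seed = 1),
               class = "prl_not_decodable")
  vals <- array(rnorm(2 * 3 * 18), c(2, 3, 18))
  expect_error(loo_decode(tensor_from_array(vals), labels, "side", seed = 1),
               class = "prl_not_decodable")
})

test_that("a single perfectly separating cell is decoded with accuracy 1", {
  labels <- balanced_labels(8)
  n <- nrow(labels)
  vals <- array(0, c(3, 4, n))
  vals[1, 2, ] <- ifelse(labels$side == "L", 1, -1)  # signal only in bin 2
  vals[2:3, , ] <- 0.01 * array(sin(seq_len(2 * 4 * n)), c(2, 4, n))
  res <- loo_decode(tensor_from_array(vals), labels, "side", seed = 5)
  expect_equal(res$accuracy[2], 1.0)
  # conservation: accuracy is exactly the mean of per-trial correctness
  expect_equal(res$accuracy, colMeans(res$correctness))
  # the separating cell carries the dominant weight at the signal bin
  expect_equal(which.max(abs(res$weights[, 2])), 1L)
  # weight sign: positive = evidence for the first level (L)
  expect_gt(res$weights[1, 2], 0)
})

test_that("label-independent activity decodes at chance", {
  tt <- small_session(8, block_length = 40)
  cells <- plant_population(30, frac_side = 0, frac_outcome = 0,
                            frac_retrieval = 0, noise_sd = 0.5)
  tm <- generate_traces(tt, cells, seed = 9)
  ep <- bin_downsample(extract_epoch(tm, tt, epoch_definition("choice")))
  labels <- trial_labels(tt)
  res <- loo_decode(ep, labels, "side", seed = 10, bins = pre_event_bin(ep))
  ci <- binomial_ci_half(nrow(labels))
  expect_gt(res$accuracy[1], ci[1])
  expect_lt(res$accuracy[1], ci[2])
})

test_that("decoding is invariant to cell permutation and common affine rescaling", {
  labels <- balanced_labels(6)
  n <- nrow(labels)
  set.seed(42)
  vals <- array(rnorm(5 * 2 * n, sd = 0.1), c(5, 2, n))
  vals[2, 1, ] <- vals[2, 1, ] + ifelse(labels$side == "L", 2, -2)
  base <- loo_decode(tensor_from_array(vals), labels, "side", seed = 6)
  perm <- c(3, 5, 2, 1, 4)
  res_p <- loo_decode(tensor_from_array(vals[perm, , , drop = FALSE]),
                      labels, "side", seed = 6)
  expect_equal(res_p$accuracy, base$accuracy)
  res_a <- loo_decode(tensor_from_array(2.5 * vals + 0.7), labels, "side",
                      seed = 6)
  expect_equal(res_a$accuracy, base$accuracy)
})

test_that("circular-shift nulls sit at chance while the real decoder does not", {
  tt <- small_session(9, block_length = 20)
  cells <- plant_population(12, frac_side = 0.5, frac_outcome = 0,
                            frac_retrieval = 0, modulation_depth = 3,
                            noise_sd = 0.3)
  tm <- generate_traces(tt, cells, seed = 11)
  ep <- bin_downsample(extract_epoch(tm, tt, epoch_definition("choice")))
  labels <- trial_labels(tt)
  b <- pre_event_bin(ep)
  real <- loo_decode(ep, labels, "side", seed = 12, bins = b)
  nul <- shuffle_null(ep, labels, "side", seed = 13, n_shuffle = 20, bins = b)
  ci <- binomial_ci_half(nrow(labels) * 20)
  expect_gt(nul$null_accuracy, ci[1])
  expect_lt(nul$null_accuracy, ci[2])
  expect_gt(real$accuracy[1], nul$null_accuracy + 0.2)
  # deterministic given (seed, n_shuffle)
  nul2 <- shuffle_null(ep, labels, "side", seed = 13, n_shuffle = 20, bins = b)
  expect_identical(nul$per_repeat, nul2$per_repeat)
  expect_error(shuffle_null(ep, labels, "side", seed = 1, n_shuffle = 0),
               class = "prl_config_error")
})

test_that("removing the highest-weight cells returns accuracy to chance", {
  tt <- small_session(10, block_length = 20)
  n_cells <- 20
  cells <- plant_population(n_cells, frac_side = 0.5, frac_outcome = 0,
                            frac_retrieval = 0, modulation_depth = 3,
                            noise_sd = 0.3)
  tm <- generate_traces(tt, cells, seed = 14)
  ep <- bin_downsample(extract_epoch(tm, tt, epoch_definition("choice")))
  labels <- trial_labels(tt)
  curve <- ablation_curve(ep, labels, "side", ks = c(0, 10), seed = 15)
  base <- loo_decode(ep, labels, "side", seed = 15,
                     bins = pre_event_bin(ep))$accuracy[1]
  expect_equal(unname(curve["k0"]), base)  # k = 0 is the baseline
  ci <- binomial_ci_half(nrow(labels))
  expect_lt(curve["k10"], ci[2])  # signal cells gone -> chance
  expect_gt(base, 0.9)
  expect_error(ablation_curve(ep, labels, "side", ks = n_cells, seed = 1),
               class = "prl_config_error")
})
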