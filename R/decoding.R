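#' Side/outcome labels and the four side-by-outcome conditions
#'
#' @param trials A `trial_table`.
#' @return Data frame with factors `side` (L/R), `outcome` (win/lose) and
#'   `condition` (LW, LU, RW, RU).
#' @export
trial_labels <- function(trials) {
  side <- factor(trials$chosen_side, levels = c("L", "R"))
  outcome <- factor(ifelse(trials$rewarded == 1, "win", "lose"),
                    levels = c("win", "lose"))
  condition <- factor(paste0(as.character(side),
                             ifelse(outcome == "win", "W", "U")),
                      levels = c("LW", "LU", "RW", "RU"))
  data.frame(side = side, outcome = outcome, condition = condition)
}

#' Draw a balanced training set for one leave-one-out fold
#'
#' After excluding the held-out trial, samples the same number `m` of trials
#' from each of the four side-by-outcome conditions (left-win, left-unrewarded,
#' right-win, right-unrewarded), where `m` is the smallest remaining condition
#' count. A fresh draw is made for every (test trial, seed) pair so repeated
#' folds sample the whole session.
#'
#' @param labels Output of [trial_labels()].
#' @param test_trial 1-based index of the held-out trial.
#' @param seed Integer seed for the draw.
#' @return Integer vector of training-trial indices (4 * m entries, never
#'   containing `test_trial`).
#' @export
balanced_train_indices <- function(labels, test_trial, seed) {
  n <- nrow(labels)
  if (test_trial < 1 || test_trial > n)
    stop_prl("test_trial out of range", "prl_config_error")
  avail <- setdiff(seq_len(n), test_trial)
  by_cond <- split(avail, labels$condition[avail])
  counts <- vapply(by_cond, length, integer(1))
  if (any(counts == 0))
    stop_prl(sprintf("session not decodable for this target: condition %s empty",
                     paste(names(counts)[counts == 0], collapse = ",")),
             "prl_not_decodable")
  m <- min(counts)
  with_seed(seed, {
    unlist(lapply(by_cond, function(idx) {
      if (length(idx) == 1) idx else sample(idx, m)
    }), use.names = FALSE)
  })
}

# Fit one linear SVM fold and return the predicted label for x_test plus the
# hyperplane weight vector oriented so positive weights favour the first
# factor level of y.
svm_fold <- function(x_train, y_train, x_test, cost, tie_seed) {
  fit <- tryCatch(
    e1071::svm(x_train, y_train, kernel = "linear", cost = cost,
               scale = FALSE),
    error = function(e) NULL)
  lev <- levels(y_train)
  if (is.null(fit)) {  # degenerate training set (e.g. all-constant features)
    pred <- with_seed(tie_seed, sample(lev, 1))
    return(list(pred = pred, w = rep(0, ncol(x_train))))
  }
  pr <- stats::predict(fit, x_test, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  pred <- as.character(pr)
  if (!is.na(dv) && dv == 0)  # point exactly on the hyperplane
    pred <- with_seed(tie_seed, sample(lev, 1))
  w <- drop(t(fit$coefs) %*% fit$SV)
  # libsvm orients the decision function toward its first internal label
  if (fit$levels[fit$labels[1]] != lev[1]) w <- -w
  list(pred = pred, w = w)
}

#' Balanced leave-one-trial-out linear decoding
#'
#' For every trial and every requested time bin, trains a binary linear
#' maximum-margin classifier (SVM, linear kernel, cost `cost`, no feature
#' scaling) on a condition-balanced sample of the remaining trials, predicts
#' the held-out trial's label, and tallies correctness. All bins of one fold
#' share one balanced training set (trials are balanced, not bins). Training
#' class priors are exactly 0.5/0.5 by construction, so chance accuracy
#' is 0.5.
#'
#' @param epoch An `epoch_tensor`.
#' @param labels Output of [trial_labels()] for the same trials.
#' @param target `"side"` or `"outcome"`.
#' @param seed Integer seed; the result is a deterministic function of
#'   (epoch, labels, target, seed).
#' @param bins Bin indices to decode (default: all bins).
#' @param cost SVM box constraint (default 1).
#' @return A `decoder_result`: list with `target`, `bins`, `accuracy`
#'   (per bin), `correctness` (trials x bins 0/1), `weights` (cells x bins,
#'   mean over folds, positive = evidence for L / win),
#'   `per_condition_train_count` (smallest per-fold balanced count `m`),
#'   `bin_centers`, `seed`.
#' @export
loo_decode <- function(epoch, labels, target = c("side", "outcome"), seed,
                       bins = NULL, cost = 1) {
  stopifnot(inherits(epoch, "epoch_tensor"))
  target <- match.arg(target)
  y <- labels[[target]]
  n_trials <- dim(epoch$values)[3]
  n_cells <- dim(epoch$values)[1]
  if (n_trials != nrow(labels))
    stop_prl("labels and epoch tensor disagree on trial count",
             "prl_config_error")
  if (is.null(bins)) bins <- seq_along(epoch$bin_centers)
  # per-bin trial-by-cell design matrices, computed once
  xb <- lapply(bins, function(b) {
    m <- t(matrix(epoch$values[, b, ], nrow = n_cells))
    colnames(m) <- paste0("c", seq_len(n_cells))
    m
  })
  correctness <- matrix(NA_integer_, n_trials, length(bins))
  wsum <- matrix(0, n_cells, length(bins))
  m_per_fold <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    fold_seed <- mix_seed(seed, t)
    train_idx <- balanced_train_indices(labels, t, fold_seed)
    m_per_fold[t] <- length(train_idx) %/% 4L
    y_train <- factor(y[train_idx], levels = levels(y))
    for (bi in seq_along(bins)) {
      res <- svm_fold(xb[[bi]][train_idx, , drop = FALSE], y_train,
                      xb[[bi]][t, , drop = FALSE], cost,
                      tie_seed = mix_seed(fold_seed, bins[bi]))
      correctness[t, bi] <- as.integer(res$pred == as.character(y[t]))
      wsum[, bi] <- wsum[, bi] + res$w
    }
  }
  structure(list(
    target = target, bins = bins, accuracy = colMeans(correctness),
    correctness = correctness, weights = wsum / n_trials,
    per_condition_train_count = min(m_per_fold),
    bin_centers = epoch$bin_centers[bins], seed = seed),
    class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf("Decoder result (%s): %d trials x %d bins\n", x$target,
              nrow(x$correctness), length(x$bins)))
  cat(sprintf("  accuracy %.3f .. %.3f (peak %.3f at bin %d)\n",
              min(x$accuracy), max(x$accuracy), max(x$accuracy),
              x$bins[which.max(x$accuracy)]))
  if (!is.null(x$shuffle_accuracy))
    cat(sprintf("  shuffle null %.3f (n_shuffle = %d)\n",
                mean(x$shuffle_accuracy), x$n_shuffle))
  invisible(x)
}

#' Shuffled-label null decoding accuracy
#'
#' Estimates chance-level decoding by rerunning the balanced leave-one-out
#' decoder with the trial labels randomly shifted. The default shift is a
#' circular rotation by a uniform offset in `[1, N - 1]` (preserves the label
#' sequence's autocorrelation); `method = "permute"` uses a full permutation
#' instead.
#'
#' @inheritParams loo_decode
#' @param n_shuffle Number of shuffle repeats (default 100).
#' @param method `"shift"` (circular rotation) or `"permute"`.
#' @return List with `null_accuracy` (per-bin mean over repeats),
#'   `per_repeat` (repeats x bins matrix), `n_shuffle`, `method`.
#' @export
shuffle_null <- function(epoch, labels, target = c("side", "outcome"), seed,
                         n_shuffle = 100L, bins = NULL, cost = 1,
                         method = c("shift", "permute")) {
  target <- match.arg(target)
  method <- match.arg(method)
  if (n_shuffle < 1) stop_prl("n_shuffle must be >= 1", "prl_config_error")
  n <- nrow(labels)
  acc <- NULL
  for (r in seq_len(n_shuffle)) {
    perm <- with_seed(mix_seed(seed, r), {
      if (method == "shift") {
        off <- sample.int(n - 1L, 1L)
        ((seq_len(n) - 1L + off) %% n) + 1L
      } else sample.int(n)
    })
    res <- loo_decode(epoch, labels[perm, , drop = FALSE], target,
                      seed = mix_seed(seed, 100000L + r), bins = bins,
                      cost = cost)
    acc <- rbind(acc, res$accuracy)
  }
  list(null_accuracy = colMeans(acc), per_repeat = acc,
       n_shuffle = as.integer(n_shuffle), method = method)
}

#' Decoding accuracy after removing the highest-weight cells
#'
#' Ranks cells by the absolute decoder weight at a reference bin (by default
#' the bin just before the anchor event) from a full balanced leave-one-out
#' decode, then removes the top `k` cells for each requested `k` and decodes
#' again with the remainder.
#'
#' @inheritParams loo_decode
#' @param ks Integer vector of removal counts (each `< n_cells`); `k = 0`
#'   reproduces the baseline.
#' @param bin Reference bin (default [pre_event_bin()] of the epoch).
#' @return Named numeric vector: accuracy at `bin` for each `k`.
#' @export
ablation_curve <- function(epoch, labels, target = c("side", "outcome"),
                           ks, seed, bin = NULL, cost = 1) {
  target <- match.arg(target)
  n_cells <- dim(epoch$values)[1]
  if (any(ks >= n_cells))
    stop_prl("cannot remove k >= n_cells cells", "prl_config_error")
  if (is.null(bin)) bin <- pre_event_bin(epoch)
  base <- loo_decode(epoch, labels, target, seed = seed, bins = bin,
                     cost = cost)
  rank_order <- order(abs(base$weights[, 1]), decreasing = TRUE)
  out <- vapply(ks, function(k) {
    if (k == 0) return(base$accuracy[1])
    keep <- setdiff(seq_len(n_cells), rank_order[seq_len(k)])
    sub <- epoch
    sub$values <- epoch$values[keep, , , drop = FALSE]
    loo_decode(sub, labels, target, seed = seed, bins = bin,
               cost = cost)$accuracy[1]
  }, numeric(1))
  names(out) <- paste0("k", ks)
  out
}
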