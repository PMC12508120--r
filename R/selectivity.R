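#' Per-cell selectivity linear model
#'
#' Fits an ordinary least-squares linear model of a cell's per-trial scalar
#' activity on the trial labels: `activity ~ side` for the Chosen Side epoch
#' and `activity ~ rewarded + side` for the Trial Outcome and Reward
#' Retrieval epochs. Side is entered as a covariate in the outcome/retrieval
#' models so that side-selective neurons do not masquerade as outcome- or
#' reward-selective. Two-sided p-values come from the coefficient t
#' statistics; a cell is selective when the epoch's coefficient of interest
#' (side for the side epoch, rewarded otherwise) has `p < 0.05`,
#' uncorrected.
#'
#' Cells whose activity has zero variance, or whose design is rank-deficient
#' (e.g. all trials on one side), are unfittable: they are returned with
#' `NA` coefficients and `selective = FALSE` so they still count in ratio
#' denominators.
#'
#' @param activity Numeric per-trial scalar activity.
#' @param side Per-trial side, `"L"`/`"R"` or 0/1 (L = 0).
#' @param rewarded Per-trial 0/1 (required for outcome/retrieval epochs).
#' @param epoch `"side"`, `"outcome"` or `"retrieval"`.
#' @param cell Optional cell identifier carried through.
#' @return A `cell_fit` list: `cell`, `epoch`, `intercept`, `beta_side`,
#'   `beta_reward`, `p_side`, `p_reward`, `selective`, `fittable`.
#' @export
fit_cell_glm <- function(activity, side, rewarded = NULL,
                         epoch = c("side", "outcome", "retrieval"),
                         cell = NA_integer_) {
  epoch <- match.arg(epoch)
  if (is.character(side) || is.factor(side))
    side <- as.integer(as.character(side) == "R")
  side <- as.numeric(side)
  n <- length(activity)
  if (n < 3) stop_prl("need at least 3 trials", "prl_precondition_error")
  if (epoch != "side") {
    if (is.null(rewarded))
      stop_prl("outcome/retrieval models need the rewarded regressor",
               "prl_config_error")
    rewarded <- as.numeric(rewarded)
  }
  unfit <- function() {
    list(cell = cell, epoch = epoch, intercept = NA_real_,
         beta_side = NA_real_, beta_reward = NA_real_, p_side = NA_real_,
         p_reward = NA_real_, selective = FALSE, fittable = FALSE)
  }
  if (stats::var(activity) == 0) return(structure(unfit(), class = "cell_fit"))
  df <- if (epoch == "side") data.frame(activity = activity, side = side)
        else data.frame(activity = activity, rewarded = rewarded, side = side)
  X <- stats::model.matrix(stats::as.formula(
    if (epoch == "side") "~ side" else "~ rewarded + side"), df)
  if (qr(X)$rank < ncol(X)) return(structure(unfit(), class = "cell_fit"))
  fit <- stats::lm(activity ~ ., data = df)
  sm <- summary(fit)$coefficients
  # a perfect (zero-residual) fit yields se = 0 and p = NaN; a nonzero
  # coefficient estimated with zero error is significant at any level
  nan_p <- is.nan(sm[, 4])
  sm[nan_p, 4] <- ifelse(abs(sm[nan_p, 1]) > 0, 0, 1)
  get <- function(term, col) if (term %in% rownames(sm)) sm[term, col] else NA_real_
  out <- list(
    cell = cell, epoch = epoch,
    intercept = get("(Intercept)", 1),
    beta_side = get("side", 1),
    beta_reward = if (epoch == "side") NA_real_ else get("rewarded", 1),
    p_side = get("side", 4),
    p_reward = if (epoch == "side") NA_real_ else get("rewarded", 4),
    fittable = TRUE)
  p_int <- if (epoch == "side") out$p_side else out$p_reward
  out$selective <- isTRUE(!is.na(p_int) && p_int < 0.05)
  structure(out, class = "cell_fit")
}

#' Fit selectivity models for every cell in an activity matrix
#'
#' @param activity Matrix cells x trials of per-trial scalar activity
#'   (e.g. pre-event bin means, or [retrieval_scalar_activity()] output).
#' @inheritParams fit_cell_glm
#' @return List of `cell_fit` objects, one per row.
#' @export
fit_cells <- function(activity, side, rewarded = NULL,
                      epoch = c("side", "outcome", "retrieval")) {
  epoch <- match.arg(epoch)
  lapply(seq_len(nrow(activity)), function(ci)
    fit_cell_glm(activity[ci, ], side, rewarded, epoch, cell = ci))
}

#' Ratio of selective cells
#'
#' @param fits List of `cell_fit` objects. Unfittable cells count in the
#'   denominator as non-selective (the denominator is all imaged neurons).
#' @return List with `n_cells`, `n_selective`, `ratio`.
#' @export
selective_ratio <- function(fits) {
  if (length(fits) == 0) stop_prl("no cell fits supplied", "prl_config_error")
  sel <- vapply(fits, function(f) isTRUE(f$selective), logical(1))
  list(n_cells = length(fits), n_selective = sum(sel),
       ratio = mean(sel))
}

#' Cross-validated peak-aligned condition-difference heatmap
#'
#' Splits trials into odd and even by session order; per cell and condition
#' computes the trial-averaged window activity; range-normalizes each cell's
#' condition averages jointly to \[0, 1\] (a constant cell maps to all
#' zeros); and forms the condition difference (left minus right for the side
#' contrast, unrewarded minus rewarded for the outcome contrast), so emitted
#' values lie in \[-1, 1\]. Peak indices are located on the odd-trial
#' differences and the returned matrix holds the held-out even-trial
#' differences in the chosen row order: by signed selectivity beta
#' (default) or by odd-trial peak index.
#'
#' @param raw An `epoch_window` (cells x frames x trials).
#' @param labels Output of [trial_labels()].
#' @param contrast `"side"` (left - right) or `"outcome"`
#'   (unrewarded - rewarded).
#' @param sort_by `"beta"` (signed coefficient, most negative first) or
#'   `"peak"` (odd-trial peak frame).
#' @return A `heatmap_matrix`: list with `values` (cells x frames, even-trial
#'   differences, row-ordered), `order` (original cell indices), `peak_index`
#'   (odd-trial peak frame per emitted row), `beta` (per emitted row),
#'   `contrast`, `sort_by`.
#' @export
peak_aligned_heatmap <- function(raw, labels, contrast = c("side", "outcome"),
                                 sort_by = c("beta", "peak")) {
  stopifnot(inherits(raw, "epoch_window"))
  contrast <- match.arg(contrast)
  sort_by <- match.arg(sort_by)
  n_trials <- dim(raw)[3]
  grp <- if (contrast == "side") labels$side == "L" else labels$outcome == "lose"
  odd <- seq(1, n_trials, by = 2)
  even <- seq(2, n_trials, by = 2)
  for (g in c(TRUE, FALSE)) {
    if (sum(grp == g) < 2)
      stop_prl("each condition needs at least 2 trials", "prl_config_error")
  }
  n_cells <- dim(raw)[1]
  n_frames <- dim(raw)[2]
  cond_mean <- function(trials_idx) {
    a <- apply(raw[, , intersect(trials_idx, which(grp)), drop = FALSE],
               c(1, 2), mean)
    b <- apply(raw[, , intersect(trials_idx, which(!grp)), drop = FALSE],
               c(1, 2), mean)
    list(a = a, b = b)
  }
  mo <- cond_mean(odd)
  me <- cond_mean(even)
  diff_odd <- matrix(NA_real_, n_cells, n_frames)
  diff_even <- matrix(NA_real_, n_cells, n_frames)
  for (ci in seq_len(n_cells)) {
    all_vals <- c(mo$a[ci, ], mo$b[ci, ], me$a[ci, ], me$b[ci, ])
    rng <- range(all_vals)
    if (diff(rng) == 0) {
      diff_odd[ci, ] <- 0
      diff_even[ci, ] <- 0
    } else {
      nrm <- function(v) (v - rng[1]) / diff(rng)
      diff_odd[ci, ] <- nrm(mo$a[ci, ]) - nrm(mo$b[ci, ])
      diff_even[ci, ] <- nrm(me$a[ci, ]) - nrm(me$b[ci, ])
    }
  }
  # selectivity beta from window-mean activity per trial
  win_mean <- t(apply(raw, c(1, 3), mean))  # trials x cells
  betas <- vapply(seq_len(n_cells), function(ci) {
    f <- fit_cell_glm(win_mean[, ci], labels$side,
                      rewarded = as.integer(labels$outcome == "win"),
                      epoch = if (contrast == "side") "side" else "outcome",
                      cell = ci)
    b <- if (contrast == "side") f$beta_side else f$beta_reward
    if (is.na(b)) 0 else b
  }, numeric(1))
  peak_idx <- apply(diff_odd, 1, function(v) which.max(abs(v)))
  ord <- if (sort_by == "beta") order(betas) else order(peak_idx)
  structure(list(values = diff_even[ord, , drop = FALSE], order = ord,
                 peak_index = peak_idx[ord], beta = betas[ord],
                 contrast = contrast, sort_by = sort_by),
            class = "heatmap_matrix")
}
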