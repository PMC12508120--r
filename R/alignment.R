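#' Epoch definition: a window around a named trial event
#'
#' Standard epochs: `initiation` (4 s centered on the initiation touch),
#' `choice` (1 s before to 3 s after the choice nosepoke) and `retrieval`
#' (1 s centered on reward-port head entry).
#'
#' @param name `"initiation"`, `"choice"` or `"retrieval"`.
#' @param anchor_event Trial-table timestamp column; defaults to the epoch's
#'   natural event (`t_init`, `t_choice`, `t_retrieval`).
#' @param window Length-2 numeric `(start_offset, end_offset)` in seconds
#'   relative to the anchor; `start_offset < end_offset`.
#' @return An `epoch_definition` list.
#' @export
epoch_definition <- function(name = c("initiation", "choice", "retrieval"),
                             anchor_event = NULL, window = NULL) {
  name <- match.arg(name)
  if (is.null(anchor_event))
    anchor_event <- switch(name, initiation = "t_init", choice = "t_choice",
                           retrieval = "t_retrieval")
  if (is.null(window))
    window <- switch(name, initiation = c(-2, 2), choice = c(-1, 3),
                     retrieval = c(-0.5, 0.5))
  if (window[1] >= window[2])
    stop_prl("window start must precede window end", "prl_config_error")
  structure(list(name = name, anchor_event = anchor_event, window = window),
            class = "epoch_definition")
}

# Nearest frame to time t (1-based); exact half-frame ties resolve to the
# earlier frame.
nearest_frame <- function(t, fps, t0 = 0) {
  as.integer(ceiling((t - t0) * fps - 0.5)) + 1L
}

#' Extract an event-aligned window from a trace matrix
#'
#' For every trial, cuts the same number of frames around the anchor event
#' (nearest frame to the anchor timestamp). Window length is
#' `round((end - start) * fps)` frames for all trials.
#'
#' @param traces A `trace_matrix`.
#' @param trials A `trial_table`.
#' @param epoch An [epoch_definition()].
#' @return An `epoch_window`: array cells x frames x trials with attributes
#'   `anchor_pos` (1-based window position of the anchor frame), `fps`,
#'   `epoch` and `trial_index_map`.
#' @export
extract_epoch <- function(traces, trials, epoch) {
  stopifnot(inherits(traces, "trace_matrix"),
            inherits(epoch, "epoch_definition"))
  fps <- traces$fps
  anchors <- trials[[epoch$anchor_event]]
  if (is.null(anchors))
    stop_prl(sprintf("trial table has no column '%s'", epoch$anchor_event),
             "prl_config_error")
  fpw <- as.integer(round((epoch$window[2] - epoch$window[1]) * fps))
  start_off <- as.integer(round(epoch$window[1] * fps))
  n_frames <- ncol(traces$values)
  n_trials <- nrow(trials)
  out <- array(NA_real_, dim = c(nrow(traces$values), fpw, n_trials))
  for (ti in seq_len(n_trials)) {
    if (is.na(anchors[ti]))
      stop_prl(sprintf("trial %d has no '%s' timestamp", ti,
                       epoch$anchor_event), "prl_bounds_error")
    af <- nearest_frame(anchors[ti], fps, traces$t0)
    f1 <- af + start_off
    f2 <- f1 + fpw - 1L
    if (f1 < 1L || f2 > n_frames)
      stop_prl(sprintf("window for trial %d spans frames %d..%d outside the trace (1..%d)",
                       ti, f1, f2, n_frames), "prl_bounds_error")
    out[, , ti] <- traces$values[, f1:f2, drop = FALSE]
  }
  structure(out, anchor_pos = 1L - start_off, fps = fps, epoch = epoch,
            trial_index_map = trials$index,
            class = c("epoch_window", "array"))
}

#' Overlapping-bin temporal downsampling
#'
#' Averages the aligned window into overlapping 6-frame bins advanced by 2
#' frames: bin 1 is the mean of frames 1--6, bin 2 of frames 3--9, and so on
#' (`floor((F - 6) / 2) + 1` bins for an F-frame window).
#'
#' @param raw An `epoch_window` from [extract_epoch()].
#' @param bin_width,bin_stride Frames per bin and bin advance (defaults 6, 2).
#' @return An `epoch_tensor`: list with `values` (cells x bins x trials),
#'   `bin_centers` (s, relative to anchor), `anchor_pos`, `fps`, `epoch`,
#'   `trial_index_map`, `bin_width`, `bin_stride`.
#' @export
bin_downsample <- function(raw, bin_width = 6L, bin_stride = 2L) {
  stopifnot(inherits(raw, "epoch_window"))
  fpw <- dim(raw)[2]
  if (fpw < bin_width)
    stop_prl(sprintf("window of %d frames is shorter than one %d-frame bin",
                     fpw, bin_width), "prl_size_error")
  n_bins <- (fpw - bin_width) %/% bin_stride + 1L
  anchor_pos <- attr(raw, "anchor_pos")
  fps <- attr(raw, "fps")
  vals <- array(NA_real_, dim = c(dim(raw)[1], n_bins, dim(raw)[3]))
  centers <- numeric(n_bins)
  rel_times <- (seq_len(fpw) - anchor_pos) / fps
  for (b in seq_len(n_bins)) {
    span <- (bin_stride * (b - 1L) + 1L):(bin_stride * (b - 1L) + bin_width)
    vals[, b, ] <- apply(raw[, span, , drop = FALSE], c(1, 3), mean)
    centers[b] <- mean(rel_times[span])
  }
  structure(list(values = vals, bin_centers = centers,
                 anchor_pos = anchor_pos, fps = fps,
                 epoch = attr(raw, "epoch"),
                 trial_index_map = attr(raw, "trial_index_map"),
                 bin_width = bin_width, bin_stride = bin_stride),
            class = "epoch_tensor")
}

#' The analysis bin just before an event
#'
#' Returns the largest bin whose constituent frames all precede the anchor
#' frame (or the anchor shifted by `offset` seconds -- e.g. `offset = 1` for
#' the bin before a reward cue delivered 1 s after choice).
#'
#' @param epoch An `epoch_tensor`.
#' @param offset Seconds added to the anchor before locating the bin.
#' @return 1-based bin index.
#' @export
pre_event_bin <- function(epoch, offset = 0) {
  stopifnot(inherits(epoch, "epoch_tensor"))
  a <- epoch$anchor_pos + as.integer(round(offset * epoch$fps))
  if (epoch$anchor_pos <= 1L)
    stop_prl("epoch window must span the anchor (start_offset < 0)",
             "prl_precondition_error")
  # bin b covers window frames (s*(b-1)+1) .. (s*(b-1)+w); need last frame < a
  w <- epoch$bin_width; s <- epoch$bin_stride
  b <- (a - 1L - w) %/% s + 1L
  n_bins <- length(epoch$bin_centers)
  if (b < 1L)
    stop_prl("no complete bin precedes the anchor", "prl_precondition_error")
  min(b, n_bins)
}

#' Per-trial scalar activity around reward retrieval
#'
#' Mean activity in a fixed-width window centered on reward-port head entry
#' on rewarded trials. Unrewarded trials use a pseudo-entry at
#' `t_choice + reward_delay + median(reward_latency)` -- a window whose
#' placement matches the center of the rewarded-trial entry distribution.
#' The window covers `2 * half_width_frames` frames (`entry - hw` to
#' `entry + hw - 1`), i.e. exactly 1 s at the default `hw = 10` and 20 fps.
#'
#' @param traces A `trace_matrix`.
#' @param trials A `trial_table` (must contain at least one rewarded trial).
#' @param half_width_frames Window half-width in frames (default 10).
#' @return Matrix cells x trials of window means.
#' @export
retrieval_scalar_activity <- function(traces, trials, half_width_frames = 10L) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (!any(trials$rewarded == 1))
    stop_prl("no rewarded trials: pseudo-entry undefined", "prl_precondition_error")
  cfg <- attr(trials, "config")
  rd <- if (!is.null(cfg)) cfg$reward_delay else
    stats::median(trials$t_reward_cue - trials$t_choice, na.rm = TRUE)
  med_lat <- stats::median(trials$reward_latency, na.rm = TRUE)
  entry <- ifelse(trials$rewarded == 1, trials$t_retrieval,
                  trials$t_choice + rd + med_lat)
  fps <- traces$fps
  hw <- as.integer(half_width_frames)
  n_frames <- ncol(traces$values)
  out <- matrix(NA_real_, nrow = nrow(traces$values), ncol = nrow(trials))
  for (ti in seq_len(nrow(trials))) {
    ef <- nearest_frame(entry[ti], fps, traces$t0)
    f1 <- ef - hw
    f2 <- ef + hw - 1L
    if (f1 < 1L || f2 > n_frames)
      stop_prl(sprintf("retrieval window for trial %d outside the trace", ti),
               "prl_bounds_error")
    out[, ti] <- rowMeans(traces$values[, f1:f2, drop = FALSE])
  }
  out
}
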