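#' Specify a synthetic cell population
#'
#' One row per cell. Each selective cell emits a calcium transient
#' (difference-of-exponentials kernel) at its locked trial event on every
#' trial, with amplitude `base_amplitude * (1 + modulation_depth)` on trials
#' matching its preferred condition and `base_amplitude` otherwise.
#' Non-selective (`"none"`) cells emit no event-locked transients. All cells
#' additionally emit spontaneous transients at `spontaneous_rate` and carry
#' additive Gaussian noise.
#'
#' @param selectivity_class Character vector: `"side"`, `"outcome"`,
#'   `"retrieval"` or `"none"`.
#' @param preferred_condition `"L"`/`"R"` for side cells, `"win"`/`"lose"`
#'   for outcome and retrieval cells; ignored for `"none"`.
#' @param locked_event `"choice"`, `"reward_cue"` or `"retrieval"`. Defaults
#'   to the class's natural event.
#' @param base_amplitude Transient peak amplitude (fluorescence units).
#' @param modulation_depth Fractional amplitude gain on preferred trials
#'   (>= 0).
#' @param kernel_rise,kernel_decay Kernel time constants, seconds
#'   (`kernel_rise < kernel_decay`; GCaMP6f-like defaults 0.05 / 0.5).
#' @param noise_sd Gaussian noise SD (>= 0, fluorescence units).
#' @param spontaneous_rate Spontaneous transient rate, events/s.
#' @param event_offset Seconds added to the locked event time. A negative
#'   offset plants anticipatory activity that precedes the event, as choice-
#'   predictive neurons do in frontal cortex.
#' @return A `cell_spec` data.frame, one row per cell.
#' @export
cell_spec <- function(selectivity_class, preferred_condition = NA_character_,
                      locked_event = NULL, base_amplitude = 1,
                      modulation_depth = 1, kernel_rise = 0.05,
                      kernel_decay = 0.5, noise_sd = 0.3,
                      spontaneous_rate = 0.05, event_offset = 0) {
  n <- length(selectivity_class)
  if (!all(selectivity_class %in% c("side", "outcome", "retrieval", "none")))
    stop_prl("unknown selectivity_class", "prl_config_error")
  if (is.null(locked_event)) {
    locked_event <- c(side = "choice", outcome = "reward_cue",
                      retrieval = "retrieval", none = "choice")[selectivity_class]
  }
  spec <- data.frame(
    cell = seq_len(n), selectivity_class = selectivity_class,
    preferred_condition = rep_len(preferred_condition, n),
    locked_event = rep_len(locked_event, n),
    base_amplitude = rep_len(base_amplitude, n),
    modulation_depth = rep_len(modulation_depth, n),
    kernel_rise = rep_len(kernel_rise, n),
    kernel_decay = rep_len(kernel_decay, n),
    noise_sd = rep_len(noise_sd, n),
    spontaneous_rate = rep_len(spontaneous_rate, n),
    event_offset = rep_len(event_offset, n), stringsAsFactors = FALSE)
  if (any(spec$kernel_rise >= spec$kernel_decay))
    stop_prl("kernel_rise must be smaller than kernel_decay",
             "prl_config_error")
  if (any(spec$noise_sd < 0) || any(spec$modulation_depth < 0))
    stop_prl("noise_sd and modulation_depth must be >= 0", "prl_config_error")
  class(spec) <- c("cell_spec", "data.frame")
  spec
}

#' Build a mixed population with planted selective fractions
#'
#' Convenience wrapper around [cell_spec()] that allocates cells to the four
#' selectivity classes. Preferred conditions alternate (L/R, win/lose) within
#' each class. Side and outcome cells default to an anticipatory
#' `event_offset` of -0.5 s so that choice- and outcome-predictive signal is
#' present in the analysis bin just before the anchor event, mirroring the
#' pre-choice ramping seen in frontal-cortex recordings.
#'
#' @param n_cells Total number of cells.
#' @param frac_side,frac_outcome,frac_retrieval Planted fractions (sum <= 1;
#'   the remainder are non-selective noise cells).
#' @param anticipation_offset Event offset (s) for side and outcome cells.
#' @param ... Further per-cell parameters passed to [cell_spec()]
#'   (`base_amplitude`, `modulation_depth`, `noise_sd`, ...).
#' @return A `cell_spec` data.frame.
#' @export
plant_population <- function(n_cells, frac_side = 0.25, frac_outcome = 0.15,
                             frac_retrieval = 0.15,
                             anticipation_offset = -0.5, ...) {
  n_side <- round(n_cells * frac_side)
  n_out <- round(n_cells * frac_outcome)
  n_ret <- round(n_cells * frac_retrieval)
  n_none <- n_cells - n_side - n_out - n_ret
  if (n_none < 0)
    stop_prl("planted fractions exceed 1", "prl_config_error")
  classes <- c(rep("side", n_side), rep("outcome", n_out),
               rep("retrieval", n_ret), rep("none", n_none))
  pref <- c(rep_len(c("L", "R"), n_side), rep_len(c("win", "lose"), n_out),
            rep_len(c("win", "lose"), n_ret), rep(NA_character_, n_none))
  offs <- c(rep(anticipation_offset, n_side + n_out), rep(0, n_ret),
            rep(0, n_none))
  cell_spec(classes, preferred_condition = pref, event_offset = offs, ...)
}

kernel_shape <- function(rise, decay, fps) {
  tt <- seq(0, decay * 6, by = 1 / fps)
  k <- exp(-tt / decay) - exp(-tt / rise)
  k / max(k)
}

# Event time per trial for a cell's locked event. Unrewarded trials have no
# reward cue or retrieval; those cells use the nominal cue time
# (choice + reward_delay) and a pseudo-entry (cue + median reward latency).
locked_event_times <- function(trials, locked_event, reward_delay = NULL) {
  if (is.null(reward_delay)) {
    rd <- stats::median(trials$t_reward_cue - trials$t_choice, na.rm = TRUE)
    if (is.na(rd)) rd <- 1
  } else rd <- reward_delay
  med_lat <- stats::median(trials$reward_latency, na.rm = TRUE)
  if (is.na(med_lat)) med_lat <- 1
  switch(locked_event,
    choice = trials$t_choice,
    reward_cue = trials$t_choice + rd,
    retrieval = ifelse(trials$rewarded == 1, trials$t_retrieval,
                       trials$t_choice + rd + med_lat),
    stop_prl("unknown locked_event", "prl_config_error"))
}

trial_is_preferred <- function(trials, class, preferred) {
  switch(class,
    side = trials$chosen_side == preferred,
    outcome = ,
    retrieval = (trials$rewarded == 1) == (preferred == "win"),
    none = rep(FALSE, nrow(trials)))
}

#' Generate detrended fluorescence traces for a simulated session
#'
#' Forward model for event-locked calcium activity: for each cell and trial
#' a difference-of-exponentials transient is inserted at the cell's locked
#' event (amplitude gated by the trial's match to the cell's preferred
#' condition), spontaneous transients are laid down as a Poisson process, and
#' Gaussian noise is added. Output is a baseline-subtracted (not normalized)
#' trace matrix sampled at `fps`.
#'
#' The noise-free component is linear in `base_amplitude`: with a fixed seed,
#' doubling all amplitudes doubles the planted signal exactly.
#'
#' @param trials A `trial_table`.
#' @param cells A [cell_spec()] data.frame.
#' @param session_duration Seconds; defaults to the last trial event + 5 s.
#' @param fps Sampling rate, frames/s (default 20).
#' @param seed Integer seed.
#' @return A `trace_matrix`: list with `values` (cells x frames),
#'   `fps`, `t0`, `frame_times`.
#' @export
generate_traces <- function(trials, cells, session_duration = NULL,
                            fps = 20, seed = 1L) {
  stopifnot(is.data.frame(cells))
  cfg <- attr(trials, "config")
  rd <- if (!is.null(cfg)) cfg$reward_delay else NULL
  t_last <- max(trials$t_choice, trials$t_retrieval, na.rm = TRUE)
  if (is.null(session_duration)) session_duration <- t_last + 5
  if (t_last >= session_duration)
    stop_prl("trial event times exceed session_duration", "prl_bounds_error")
  n_frames <- as.integer(floor(session_duration * fps)) + 1L
  frame_times <- (seq_len(n_frames) - 1) / fps
  values <- matrix(0, nrow = nrow(cells), ncol = n_frames)
  with_seed(seed, {
    for (ci in seq_len(nrow(cells))) {
      cell <- cells[ci, ]
      k <- kernel_shape(cell$kernel_rise, cell$kernel_decay, fps)
      row <- numeric(n_frames)
      if (cell$selectivity_class != "none" && cell$base_amplitude != 0) {
        ev <- locked_event_times(trials, cell$locked_event, rd) +
          cell$event_offset
        if (any(ev > session_duration, na.rm = TRUE))
          stop_prl("locked event beyond session_duration", "prl_bounds_error")
        pref <- trial_is_preferred(trials, cell$selectivity_class,
                                   cell$preferred_condition)
        amp <- cell$base_amplitude * (1 + cell$modulation_depth * pref)
        for (ti in seq_along(ev)) {
          f0 <- max(1L, as.integer(round(ev[ti] * fps)) + 1L)
          span <- f0:min(n_frames, f0 + length(k) - 1L)
          row[span] <- row[span] + amp[ti] * k[seq_along(span)]
        }
      }
      if (cell$spontaneous_rate > 0) {
        n_ev <- stats::rpois(1, cell$spontaneous_rate * session_duration)
        if (n_ev > 0) {
          ev_t <- stats::runif(n_ev, 0, session_duration)
          for (et in ev_t) {
            f0 <- as.integer(round(et * fps)) + 1L
            span <- f0:min(n_frames, f0 + length(k) - 1L)
            row[span] <- row[span] + cell$base_amplitude * k[seq_along(span)]
          }
        }
      }
      if (cell$noise_sd > 0) row <- row + stats::rnorm(n_frames, 0, cell$noise_sd)
      values[ci, ] <- row
    }
  })
  structure(list(values = values, fps = fps, t0 = 0,
                 frame_times = frame_times),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("Trace matrix: %d cells x %d frames at %g fps (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$fps,
              ncol(x$values) / x$fps))
  invisible(x)
}
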