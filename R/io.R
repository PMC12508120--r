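# On-disk formats: tab-separated text throughout. Matrix files carry their
# metadata (fps, t0, provenance stamps) as '#key=value' header comments.

read_header_meta <- function(path) {
  meta <- list()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !startsWith(line, "#")) break
    kv <- sub("^#", "", line)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  meta
}

meta_header <- function(meta) {
  if (length(meta) == 0) return(character(0))
  sprintf("#%s=%s", names(meta), vapply(meta, as.character, character(1)))
}

trial_table_columns <- c(
  "index", "block", "better_side", "chosen_side", "rewarded",
  "better_chosen", "t_init_cue", "t_init", "t_choice", "t_reward_cue",
  "t_retrieval", "init_latency", "choice_latency", "reward_latency")

#' Write / read a trial table as tab-separated text
#'
#' Columns are exactly the trial-table fields, times in seconds, 1-based
#' trial indices. Provenance (seed, configuration hash) is embedded as
#' `#key=value` comment lines before the header. Reading validates the type
#' invariants: required columns, strictly increasing within-trial
#' timestamps, equal block sizes, and consistency of the better-chosen
#' indicator.
#'
#' @param trials A `trial_table`.
#' @param path File path.
#' @param meta Named list written as header comments (e.g. `seed`,
#'   `config_hash`).
#' @return `write_trial_table` returns `path` invisibly; `read_trial_table`
#'   returns a validated `trial_table` with the parsed header in
#'   `attr(, "meta")`.
#' @export
write_trial_table <- function(trials, path, meta = list()) {
  cfg <- attr(trials, "config")
  if (!is.null(cfg) && is.null(meta$config_hash))
    meta$config_hash <- fnv1a_hash(jsonlite::toJSON(unclass(cfg),
                                                    auto_unbox = TRUE))
  lines <- meta_header(meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  utils::write.table(as.data.frame(trials)[, trial_table_columns], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @param validate Check type invariants on read (default TRUE).
#' @export
read_trial_table <- function(path, validate = TRUE) {
  meta <- read_header_meta(path)
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(trial_table_columns, names(df))
  if (length(missing) > 0)
    stop_prl(sprintf("trial table missing column(s): %s",
                     paste(missing, collapse = ", ")), "prl_validation_error")
  df <- df[, trial_table_columns]
  if (validate) validate_trial_table(df)
  attr(df, "meta") <- meta
  class(df) <- c("trial_table", "data.frame")
  df
}

validate_trial_table <- function(df) {
  for (i in seq_len(nrow(df))) {
    ts <- c(df$t_init_cue[i], df$t_init[i], df$t_choice[i])
    if (df$rewarded[i] == 1) ts <- c(ts, df$t_reward_cue[i], df$t_retrieval[i])
    if (any(is.na(ts)) || any(diff(ts) <= 0))
      stop_prl(sprintf("row %d: timestamps not strictly increasing", i),
               "prl_validation_error")
    if (df$better_chosen[i] !=
        as.integer(df$chosen_side[i] == df$better_side[i]))
      stop_prl(sprintf("row %d: better_chosen inconsistent with sides", i),
               "prl_validation_error")
  }
  sizes <- table(df$block)
  if (length(unique(as.integer(sizes))) != 1)
    stop_prl(sprintf("unequal block sizes: %s",
                     paste(as.integer(sizes), collapse = ", ")),
             "prl_validation_error")
  invisible(TRUE)
}

#' Write / read a trace matrix as wide tab-separated text
#'
#' One row per cell, one column per frame; sampling rate (`fps`, mandatory)
#' and `t0` are stored as `#key=value` header comments along with any
#' provenance entries.
#'
#' @param traces A `trace_matrix`.
#' @param path File path.
#' @param meta Extra named header entries.
#' @return `write_traces` returns `path` invisibly; `read_traces` returns a
#'   `trace_matrix`.
#' @export
write_traces <- function(traces, path, meta = list()) {
  stopifnot(inherits(traces, "trace_matrix"))
  meta$fps <- traces$fps
  meta$t0 <- traces$t0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(meta), con)
  utils::write.table(traces$values, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  meta <- read_header_meta(path)
  if (is.null(meta$fps))
    stop_prl("trace file has no fps attribute", "prl_format_error")
  fps <- as.numeric(meta$fps)
  t0 <- as.numeric(meta$t0 %||% 0)
  values <- as.matrix(utils::read.table(path, comment.char = "#", sep = "\t",
                                        header = FALSE))
  dimnames(values) <- NULL
  structure(list(values = values, fps = fps, t0 = t0,
                 frame_times = t0 + (seq_len(ncol(values)) - 1) / fps),
            class = "trace_matrix")
}
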