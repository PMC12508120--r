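#' Trial-level design matrix for choice (learning/performance) models
#'
#' Stacks sessions into one trial-level design with response
#' `better_chosen` (0/1) and predictors `TrialNum` (1..N within each
#' session), `Block` (1--3), `Schedule`, `Session` (experimental day),
#' `Area` (0 = OFC, 1 = M2) and, when present in the metadata, `Drug`
#' (0 = VEH, 1 = CNO), `Order` and `Sex` (0 = female, 1 = male). The subject
#' id is carried for random-intercept fitting.
#'
#' @param sessions List of `trial_table` objects.
#' @param metadata Data frame with one row per session; required columns
#'   `subject`, `area`, `schedule`, `session`; optional `drug`, `order`,
#'   `sex`. `area` may be 0/1 or `"OFC"`/`"M2"`.
#' @return A `design_matrix` list: `response`, `predictors` (data.frame),
#'   `subject`, `family = "binomial"`.
#' @export
build_choice_design <- function(sessions, metadata) {
  req <- c("subject", "area", "schedule", "session")
  if (!all(req %in% names(metadata)))
    stop_prl(sprintf("metadata missing column(s): %s",
                     paste(setdiff(req, names(metadata)), collapse = ", ")),
             "prl_config_error")
  if (length(sessions) != nrow(metadata))
    stop_prl("one metadata row per session required", "prl_config_error")
  area <- code_binary(metadata$area, zero = "OFC", one = "M2")
  rows <- lapply(seq_along(sessions), function(i) {
    tt <- sessions[[i]]
    d <- data.frame(
      response = tt$better_chosen, TrialNum = seq_len(nrow(tt)),
      Block = tt$block, Schedule = metadata$schedule[i],
      Session = metadata$session[i], Area = area[i],
      subject = metadata$subject[i], stringsAsFactors = FALSE)
    if (!is.null(metadata$drug))
      d$Drug <- code_binary(metadata$drug, zero = "VEH", one = "CNO")[i]
    if (!is.null(metadata$order)) d$Order <- metadata$order[i]
    if (!is.null(metadata$sex))
      d$Sex <- code_binary(metadata$sex, zero = "F", one = "M")[i]
    d
  })
  df <- do.call(rbind, rows)
  structure(list(response = df$response,
                 predictors = df[, setdiff(names(df), c("response", "subject")),
                                 drop = FALSE],
                 subject = df$subject, family = "binomial"),
            class = "design_matrix")
}

code_binary <- function(x, zero, one) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1)))
      stop_prl("binary coding columns must be 0/1", "prl_config_error")
    return(as.numeric(x))
  }
  if (!all(x %in% c(zero, one)))
    stop_prl(sprintf("expected values '%s'/'%s'", zero, one),
             "prl_config_error")
  as.numeric(x == one)
}

#' Session-level design matrix for decoding-accuracy models
#'
#' One row per session: response is the session's decoding accuracy at the
#' designated pre-event bin (the bin before choice for Chosen Side, the bin
#' before the reward cue -- choice + 1 s -- for Trial Outcome); predictors
#' are `Area`, `Schedule`, `Session`, `NumCells` and the behavioural
#' strategy measures (`WS`, `LS`, `PerseverationIndex`, `FlexibilityIndex`,
#' latency medians). `interactions = TRUE` adds `Area x` columns for the
#' strategy measures.
#'
#' @param accuracy Numeric vector of per-session accuracies in \[0, 1\]
#'   (extract with `result$accuracy[...]` at [pre_event_bin()]).
#' @param behavior List of [behavior_summary()] objects, one per session.
#' @param metadata Data frame with columns `subject`, `area`, `schedule`,
#'   `session`, `n_cells`.
#' @param interactions Add Area-by-strategy interaction columns.
#' @return A `design_matrix` with `family = "gaussian"`.
#' @export
build_accuracy_design <- function(accuracy, behavior, metadata,
                                  interactions = FALSE) {
  n <- length(accuracy)
  if (length(behavior) != n || nrow(metadata) != n)
    stop_prl("accuracy, behavior and metadata must cover the same sessions",
             "prl_config_error")
  if (any(accuracy < 0 | accuracy > 1))
    stop_prl("accuracies must lie in [0, 1]", "prl_config_error")
  req <- c("subject", "area", "schedule", "session", "n_cells")
  if (!all(req %in% names(metadata)))
    stop_prl(sprintf("metadata missing column(s): %s",
                     paste(setdiff(req, names(metadata)), collapse = ", ")),
             "prl_config_error")
  g <- function(f) vapply(behavior, function(b) as.numeric(b[[f]]), numeric(1))
  pred <- data.frame(
    Area = code_binary(metadata$area, "OFC", "M2"),
    Schedule = metadata$schedule, Session = metadata$session,
    NumCells = metadata$n_cells,
    WS = g("win_stay"), LS = g("lose_shift"),
    PerseverationIndex = g("perseveration_index"),
    FlexibilityIndex = g("flexibility_index"),
    InitLatency = g("median_init_latency"),
    ChoiceLatency = g("median_choice_latency"),
    RewardLatency = g("median_reward_latency"))
  if (interactions) {
    for (v in c("WS", "LS", "PerseverationIndex", "FlexibilityIndex"))
      pred[[paste0("Area_x_", v)]] <- pred$Area * pred[[v]]
  }
  structure(list(response = accuracy, predictors = pred,
                 subject = metadata$subject, family = "gaussian"),
            class = "design_matrix")
}

#' Fit a (mixed-effects) generalized linear model to a design matrix
#'
#' Delegates fitting to `stats::glm` or, when a random subject intercept is
#' requested and the design has at least 3 subjects, to `lme4::glmer` /
#' `lme4::lmer`. Mixed-model p-values use the Wald normal approximation.
#' The contract of this function is design handling and result packaging;
#' estimation itself is standard maximum likelihood.
#'
#' @param design A `design_matrix`.
#' @param predictors Optional character vector restricting the fixed-effect
#'   terms (default: all predictor columns).
#' @param random_intercept Fit a per-subject random intercept when the
#'   design has >= 3 subjects (fixed-effects fallback otherwise).
#' @return A `glm_fit` list: `family`, `formula`, `coefficients` (data.frame
#'   with estimate, se, stat, p), `converged`, `mixed`.
#' @export
fit_glm <- function(design, predictors = NULL, random_intercept = TRUE) {
  stopifnot(inherits(design, "design_matrix"))
  if (is.null(predictors)) predictors <- names(design$predictors)
  df <- design$predictors[, predictors, drop = FALSE]
  df$.response <- design$response
  df$.subject <- design$subject
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(predictors, collapse = " + "))), df)
  if (qr(X)$rank < ncol(X))
    stop_prl("design matrix is rank-deficient (collinear or constant columns)",
             "prl_rank_error")
  fixed <- paste(".response ~", paste(predictors, collapse = " + "))
  use_mixed <- random_intercept && length(unique(design$subject)) >= 3
  if (use_mixed) {
    form <- stats::as.formula(paste(fixed, "+ (1 | .subject)"))
    fit <- if (design$family == "binomial")
      lme4::glmer(form, data = df, family = stats::binomial())
    else lme4::lmer(form, data = df, REML = FALSE)
    sm <- as.data.frame(summary(fit)$coefficients)
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    stat <- est / se
    p <- 2 * stats::pnorm(-abs(stat))
    conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
    coefs <- data.frame(term = rownames(sm), estimate = est, se = se,
                        stat = stat, p = p, row.names = NULL)
    form_txt <- paste(fixed, "+ (1 | subject)")
  } else {
    form <- stats::as.formula(fixed)
    fit <- stats::glm(form, data = df,
                      family = if (design$family == "binomial")
                        stats::binomial() else stats::gaussian())
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                        stat = sm[, 3], p = sm[, 4], row.names = NULL)
    conv <- fit$converged %||% TRUE
    form_txt <- fixed
  }
  structure(list(family = design$family, formula = form_txt,
                 coefficients = coefs, converged = conv, mixed = use_mixed),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("GLM fit (%s%s): %s\n", x$family,
              if (x$mixed) ", random subject intercept" else "", x$formula))
  print(x$coefficients, digits = 3)
  invisible(x)
}
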