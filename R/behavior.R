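## Signal-detection outcomes, d-prime, and reversal-learning metrics for
## three-port operant sessions.

#' Classify trials into signal-detection outcomes
#'
#' Each stimulus onset defines one trial. The response is poking a stimulus's
#' port *first*, within `response_window_s` of onset. For each of the three
#' stimuli and each trial: present stimulus + first poke at its port = hit;
#' present + first poke elsewhere or absent = miss; absent stimulus + first
#' poke at its port = false alarm; absent + first poke elsewhere (or no poke)
#' = correct rejection. Every trial therefore contributes one outcome to each
#' stimulus's table. Pokes at non-task ports produce misses for the present
#' stimulus and correct rejections for the absent ones. Pokes preceding the
#' first stimulus are ignored.
#'
#' @param session A [behavior_session()].
#' @param response_window_s Response window after onset, seconds (10).
#' @return An `outcome_table`: data frame with rows `A`, `V`, `AV` and
#'   columns `n_hit`, `n_miss`, `n_false_alarm`, `n_correct_rejection`, plus
#'   attribute `trials` (per-trial stimulus, first-poke port and latency).
#' @export
classify_trials <- function(session, response_window_s = 10) {
  stopifnot(inherits(session, "behavior_session"))
  onsets <- session[session$event == "stimulus_onset", , drop = FALSE]
  pokes <- session[session$event == "poke", , drop = FALSE]
  n_pre <- sum(pokes$time_s < min(c(onsets$time_s, Inf)))
  if (n_pre > 0) message(n_pre, " poke(s) before first stimulus ignored")
  stim <- names(stimulus_port_map())
  counts <- matrix(0L, nrow = 3, ncol = 4,
                   dimnames = list(stim, c("n_hit", "n_miss", "n_false_alarm",
                                           "n_correct_rejection")))
  n_tr <- nrow(onsets)
  first_port <- rep(NA_character_, n_tr)
  latency <- rep(NA_real_, n_tr)
  for (i in seq_len(n_tr)) {
    t0 <- onsets$time_s[i]
    in_win <- pokes$time_s >= t0 & pokes$time_s <= t0 + response_window_s
    if (any(in_win)) {
      j <- which(in_win)[which.min(pokes$time_s[in_win])]
      first_port[i] <- pokes$detail[j]
      latency[i] <- pokes$time_s[j] - t0
    }
    present <- onsets$detail[i]
    for (s in stim) {
      port_s <- stimulus_port_map()[[s]]
      poked_s <- !is.na(first_port[i]) && first_port[i] == port_s
      if (s == present) {
        counts[s, if (poked_s) "n_hit" else "n_miss"] <-
          counts[s, if (poked_s) "n_hit" else "n_miss"] + 1L
      } else {
        counts[s, if (poked_s) "n_false_alarm" else "n_correct_rejection"] <-
          counts[s, if (poked_s) "n_false_alarm" else "n_correct_rejection"] + 1L
      }
    }
  }
  out <- as.data.frame(counts)
  out$stimulus <- stim
  out <- out[, c("stimulus", "n_hit", "n_miss", "n_false_alarm",
                 "n_correct_rejection")]
  attr(out, "trials") <- data.frame(trial = seq_len(n_tr),
                                    stimulus = onsets$detail,
                                    first_port = first_port,
                                    latency_s = latency)
  class(out) <- c("outcome_table", "data.frame")
  out
}

#' Hit and false-alarm rates
#'
#' `HR = hits / (hits + misses)` and `FR = false alarms / (false alarms +
#' correct rejections)`, per stimulus. A zero denominator yields `NA` (the
#' rate is absent; [dprime()] then reports `NA`).
#'
#' @param table An [classify_trials()] outcome table.
#' @return Data frame with columns `stimulus`, `HR`, `FR`, `n_signal`
#'   (hits+misses), `n_noise` (FA+CR).
#' @export
rates <- function(table) {
  stopifnot(inherits(table, "outcome_table"))
  n_sig <- table$n_hit + table$n_miss
  n_noi <- table$n_false_alarm + table$n_correct_rejection
  data.frame(
    stimulus = table$stimulus,
    HR = ifelse(n_sig > 0, table$n_hit / n_sig, NA_real_),
    FR = ifelse(n_noi > 0, table$n_false_alarm / n_noi, NA_real_),
    n_signal = n_sig, n_noise = n_noi
  )
}

#' Sensitivity index d'
#'
#' `d' = Z(HR) - Z(FR)` with `Z` the standard-normal quantile function.
#' Extreme rates would give infinite quantiles, so by default a rate of 0 is
#' replaced by `1/(2N)` and a rate of 1 by `1 - 1/(2N)`, where `N` is the
#' relevant trial count (`n_signal` for HR, `n_noise` for FR).
#'
#' @param HR,FR Hit and false-alarm rates in `[0, 1]` (vectorized).
#' @param n_signal,n_noise Trial counts behind each rate (needed only when a
#'   rate is exactly 0 or 1).
#' @param correct Apply the extreme-rate correction (default `TRUE`).
#' @return d' (numeric, `NA` where either rate is missing).
#' @export
#' @examples
#' dprime(0.8413, 0.1587)  # ~ 2
dprime <- function(HR, FR, n_signal = NULL, n_noise = NULL, correct = TRUE) {
  fix <- function(r, n) {
    if (!correct) return(r)
    at0 <- !is.na(r) & r == 0
    at1 <- !is.na(r) & r == 1
    if (any(at0 | at1) && is.null(n)) {
      stop("trial counts needed to correct extreme rates", call. = FALSE)
    }
    if (!is.null(n)) {
      r[at0] <- 1 / (2 * n[at0])
      r[at1] <- 1 - 1 / (2 * n[at1])
    }
    r
  }
  if (!is.null(n_signal)) n_signal <- rep_len(n_signal, length(HR))
  if (!is.null(n_noise)) n_noise <- rep_len(n_noise, length(FR))
  stats::qnorm(fix(HR, n_signal)) - stats::qnorm(fix(FR, n_noise))
}

#' First-poke latencies split by outcome
#'
#' Latency is the time from stimulus onset to the first poke within the
#' response window, regardless of port. Trials without a poke contribute no
#' latency. Outcomes are `"hit"` (first poke at the present stimulus's port)
#' versus `"miss"` (any other first poke).
#'
#' @param session A [behavior_session()].
#' @param response_window_s Response window, seconds.
#' @return Data frame `stimulus`, `outcome`, `latency_s` (one row per poked
#'   trial) with attribute `means` (mean latency per stimulus x outcome).
#' @export
poke_latencies <- function(session, response_window_s = 10) {
  tab <- classify_trials(session, response_window_s)
  tr <- attr(tab, "trials")
  poked <- tr[!is.na(tr$first_port), , drop = FALSE]
  outcome <- ifelse(poked$first_port ==
                      stimulus_port_map()[poked$stimulus],
                    "hit", "miss")
  out <- data.frame(stimulus = poked$stimulus, outcome = outcome,
                    latency_s = poked$latency_s)
  means <- stats::aggregate(latency_s ~ stimulus + outcome, data = out, FUN = mean)
  attr(out, "means") <- means
  out
}

#' Per-stimulus hit percentage with the 3-port chance level
#'
#' @param table An [classify_trials()] outcome table.
#' @return Data frame `stimulus`, `percent_hit`, `chance_percent` (100/3).
#' @export
percent_hits <- function(table) {
  r <- rates(table)
  data.frame(stimulus = r$stimulus, percent_hit = 100 * r$HR,
             chance_percent = 100 / 3)
}

#' Exponential moving average of performance
#'
#' `e_t = e_{t-1} + (x_t - e_{t-1}) * (1 - exp(-1/tau))`, started at the
#' chance level `e_0 = 0.5`. With tau = 12 this is the smoothing used to
#' track reversal-task performance trial by trial.
#'
#' @param x Binary correct/incorrect sequence (0/1 or logical).
#' @param tau Smoothing time constant in trials (12).
#' @param init Starting value (0.5 = chance).
#' @return Numeric trace, same length as `x` (empty input gives an empty
#'   trace), bounded in `[0, 1]` for binary input.
#' @export
ema_performance <- function(x, tau = 12, init = 0.5) {
  x <- as.numeric(x)
  alpha <- 1 - exp(-1 / tau)
  out <- numeric(length(x))
  e <- init
  for (t in seq_along(x)) {
    e <- e + (x[t] - e) * alpha
    out[t] <- e
  }
  out
}

#' Reversal trigger rule
#'
#' Applies the block-transition rule to an EMA performance trace: whenever
#' the EMA exceeds `threshold` and no reversal is pending, a reversal is
#' scheduled a uniformly drawn `delay_range[1]`–`delay_range[2]` trials later
#' (taking effect before that trial). After a reversal the rule re-arms
#' immediately, so a persistently supra-threshold trace keeps cycling blocks.
#'
#' @param ema_trace Numeric EMA trace (see [ema_performance()]).
#' @param threshold Performance threshold (0.8).
#' @param delay_range Integer range of the trigger delay in trials
#'   (`c(5, 10)`).
#' @param seed Optional seed for the delay draws.
#' @return Integer vector of reversal trial indices (possibly empty).
#' @export
reversal_engine <- function(ema_trace, threshold = 0.8,
                            delay_range = c(5, 10), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  boundaries <- integer(0)
  pending <- NA_integer_
  for (t in seq_along(ema_trace)) {
    if (!is.na(pending) && t == pending) {
      boundaries <- c(boundaries, t)
      pending <- NA_integer_
    }
    if (is.na(pending) && ema_trace[t] > threshold) {
      pending <- t + sample(delay_range[1]:delay_range[2], 1)
    }
  }
  boundaries
}

#' Choice alignment around block transitions
#'
#' Averages the indicator "chose the currently high-probability port" at each
#' lag in `-window:window` around every reversal (lag 0 = first trial of the
#' new block), then averages over blocks. Lags with no data across all
#' blocks are `NA`; with no boundaries the result is all-`NA`.
#'
#' @param choices Data frame with columns `port` and `good_port` (e.g. from
#'   [simulate_behavior_session()] reversal output).
#' @param boundaries Reversal trial indices.
#' @param window Lags on each side of the transition (10).
#' @return Data frame `lag`, `p_high_port`.
#' @export
transition_alignment <- function(choices, boundaries, window = 10) {
  lags <- -window:window
  if (length(boundaries) == 0) {
    return(data.frame(lag = lags, p_high_port = NA_real_))
  }
  correct <- choices$port == choices$good_port
  n <- nrow(choices)
  acc <- matrix(NA_real_, nrow = length(boundaries), ncol = length(lags))
  for (b in seq_along(boundaries)) {
    idx <- boundaries[b] + lags
    ok <- idx >= 1 & idx <= n
    acc[b, ok] <- as.numeric(correct[idx[ok]])
  }
  data.frame(lag = lags, p_high_port = colMeans(acc, na.rm = TRUE))
}

#' Lagged logistic regression of choices
#'
#' Fits `P(choose left)` by maximum-likelihood logistic regression on three
#' +/-1-coded predictors from the previous trial: choice (left = +1), outcome
#' (rewarded = +1), and their interaction (+1 when the previous trial was a
#' rewarded left or unrewarded right choice — the win-stay/lose-shift
#' direction). Separation (perfectly predictive regressors) is detected and
#' flagged; coefficients are still reported.
#'
#' @param choices Data frame with columns `port` and `rewarded`; >= 50 trials.
#' @return List with `coefficients` (intercept, prev_choice, prev_outcome,
#'   interaction), `separation` flag and the fitted `model`.
#' @export
lagged_choice_model <- function(choices) {
  n <- nrow(choices)
  if (n < 50) stop("need >= 50 trials", call. = FALSE)
  y <- as.numeric(choices$port[-1] == "left")
  prev_choice <- ifelse(choices$port[-n] == "left", 1, -1)
  prev_outcome <- ifelse(choices$rewarded[-n], 1, -1)
  dat <- data.frame(y = y, prev_choice = prev_choice,
                    prev_outcome = prev_outcome,
                    interaction = prev_choice * prev_outcome)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ prev_choice + prev_outcome + interaction, data = dat,
               family = stats::binomial(),
               control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- stats::coef(fit)
  # a deterministic policy can separate without tripping a glm warning
  if (any(abs(co[-1]) > 15, na.rm = TRUE)) sep <- TRUE
  if (sep) warning("separation detected; coefficients are unstable",
                   call. = FALSE)
  names(co) <- c("intercept", "prev_choice", "prev_outcome", "interaction")
  list(coefficients = co, separation = sep, model = fit)
}

#' Summary of one multimodal conditioning session
#'
#' Convenience wrapper: outcomes, rates, per-stimulus d', hit percentages and
#' poke latencies.
#'
#' @param session A [behavior_session()].
#' @param response_window_s Response window, seconds.
#' @return List of class `multimodal_analysis` with `outcomes`, `rates`,
#'   `dprime`, `percent_hits`, `latencies`.
#' @export
analyze_multimodal_session <- function(session, response_window_s = 10) {
  tab <- classify_trials(session, response_window_s)
  r <- rates(tab)
  d <- dprime(r$HR, r$FR, r$n_signal, r$n_noise)
  structure(list(
    outcomes = tab, rates = r,
    dprime = data.frame(stimulus = r$stimulus, dprime = d),
    percent_hits = percent_hits(tab),
    latencies = poke_latencies(session, response_window_s)
  ), class = "multimodal_analysis")
}

#' @export
print.multimodal_analysis <- function(x, ...) {
  cat("<multimodal_analysis>\n")
  df <- merge(x$rates[, c("stimulus", "HR", "FR")], x$dprime, by = "stimulus")
  print(df, row.names = FALSE)
  invisible(x)
}
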