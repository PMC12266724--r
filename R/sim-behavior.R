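#' Construct a behavior session event log
#'
#' @param events Data frame with columns `time_s` (nondecreasing), `event`
#'   (`"stimulus_onset"`, `"poke"` or `"reward"`) and `detail` (stimulus label
#'   `A`/`V`/`AV` for onsets, port label `left`/`right`/`center`/`other` for
#'   pokes and rewards).
#' @return A `behavior_session` object (data frame).
#' @export
behavior_session <- function(events) {
  stopifnot(all(c("time_s", "event", "detail") %in% names(events)))
  if (nrow(events) > 1 && is.unsorted(events$time_s)) {
    stop("event times must be nondecreasing", call. = FALSE)
  }
  stopifnot(all(events$event %in% c("stimulus_onset", "poke", "reward")))
  stim <- events$detail[events$event == "stimulus_onset"]
  stopifnot(all(stim %in% c("A", "V", "AV")))
  pk <- events$detail[events$event %in% c("poke", "reward")]
  stopifnot(all(pk %in% c("left", "right", "center", "other")))
  structure(as.data.frame(events),
            class = c("behavior_session", "data.frame"))
}

#' Stimulus-to-port mapping of the multimodal conditioning task
#'
#' The auditory stimulus signals reward at the left port, the visual at the
#' right port, and the audiovisual at the center port.
#' @return Named character vector mapping `A`, `V`, `AV` to ports.
#' @export
stimulus_port_map <- function() {
  c(A = "left", V = "right", AV = "center")
}

#' Agents for the multimodal conditioning task
#'
#' An agent is a list with a `p_first` matrix (rows `A`, `V`, `AV`; columns
#' `left`, `right`, `center`, `other`) giving the probability that the first
#' poke after each stimulus lands on each port (row sums <= 1, the remainder
#' being no poke within the response window), and `latency_mean_s`, the mean
#' of the exponential first-poke latency.
#'
#' `agent_perfect()` always first-pokes the correct port; `agent_uniform()`
#' picks among the three task ports uniformly; `agent_absent()` never pokes;
#' `agent_rates(h, f)` first-pokes the correct port with probability `h` and
#' each incorrect task port with probability `f` (requires `h + 2f <= 1`), so
#' that downstream hit and false-alarm rates converge to `h` and `f`.
#'
#' @param h,f Target hit and false-alarm probabilities.
#' @param latency_mean_s Mean first-poke latency, seconds.
#' @return An agent parameter list.
#' @export
agent_rates <- function(h, f, latency_mean_s = 1) {
  if (any(c(h, f) < 0) || any(c(h, f) > 1) || h + 2 * f > 1) {
    stop("need 0 <= h, f and h + 2f <= 1", call. = FALSE)
  }
  stim <- names(stimulus_port_map())
  ports <- c("left", "right", "center", "other")
  p <- matrix(0, 3, 4, dimnames = list(stim, ports))
  for (s in stim) {
    p[s, stimulus_port_map()[[s]]] <- h
    p[s, setdiff(ports[1:3], stimulus_port_map()[[s]])] <- f
  }
  list(p_first = p, latency_mean_s = latency_mean_s)
}

#' @rdname agent_rates
#' @export
agent_perfect <- function(latency_mean_s = 1) agent_rates(1, 0, latency_mean_s)

#' @rdname agent_rates
#' @export
agent_uniform <- function(latency_mean_s = 1) {
  agent_rates(1 / 3, 1 / 3, latency_mean_s)
}

#' @rdname agent_rates
#' @export
agent_absent <- function() {
  a <- agent_rates(0, 0)
  a$p_first[] <- 0
  a
}

#' Simulate a behavioral session
#'
#' For `task = "multimodal"`: draws `n_trials` stimuli uniformly from
#' `A`/`V`/`AV` separated by 1–2 min inter-trial intervals, samples the
#' agent's first poke (port and exponential latency) per trial, and emits a
#' reward event when the correct port is poked first. For
#' `task = "reversal"`: runs the two-port probabilistic task engine — the good
#' port rewards at `config$reward_p_good` (85%), the bad at
#' `config$reward_p_bad` (15%); performance is tracked by an exponential
#' moving average (tau = 12) and reward contingencies reverse 5–10 trials
#' after the EMA crosses 0.8 (see [reversal_engine()]).
#'
#' @param config A [sim_config()] (its `seed` drives all randomness).
#' @param agent_params For `"multimodal"`, an agent list (see
#'   [agent_rates()]); for `"reversal"`, `list(policy = ...)` with policy one
#'   of `"perfect"`, `"chance"`, `"wsls"` (win-stay/lose-shift) or
#'   `"perseverative"` (repeats its previous choice with probability 0.9).
#' @param task `"multimodal"` or `"reversal"`.
#' @param n_trials Trials to simulate; defaults to 30 for the multimodal task
#'   (one session) and 300 for reversal.
#' @return For `"multimodal"`, a [behavior_session()] with attribute
#'   `"truth"` (per-trial stimulus and first-poke record). For `"reversal"`,
#'   a `reversal_session`: list with `choices` (data frame `trial`, `port`,
#'   `good_port`, `rewarded`, `correct`, `block_id`), `ema_trace` and
#'   `boundaries`.
#' @export
simulate_behavior_session <- function(config, agent_params,
                                      task = c("multimodal", "reversal"),
                                      n_trials = NULL) {
  task <- match.arg(task)
  set.seed(config$seed + 4L)
  if (task == "multimodal") {
    if (is.null(n_trials)) n_trials <- 30L
    simulate_multimodal(config, agent_params, n_trials)
  } else {
    if (is.null(n_trials)) n_trials <- 300L
    simulate_reversal(config, agent_params, n_trials)
  }
}

simulate_multimodal <- function(config, agent, n_trials) {
  p <- agent$p_first
  if (any(p < 0) || any(p > 1) || any(rowSums(p) > 1 + 1e-12)) {
    stop("agent poke probabilities must lie in [0, 1] with row sums <= 1",
         call. = FALSE)
  }
  stim <- sample(c("A", "V", "AV"), n_trials, replace = TRUE)
  onsets <- cumsum(runif(n_trials, 60, 120))
  ports <- colnames(p)
  ev <- list()
  for (i in seq_len(n_trials)) {
    ev[[length(ev) + 1]] <- data.frame(time_s = onsets[i],
                                       event = "stimulus_onset",
                                       detail = stim[i])
    pr <- p[stim[i], ]
    draw <- sample(c(ports, "none"), 1, prob = c(pr, 1 - sum(pr)))
    if (draw != "none") {
      lat <- rexp(1, 1 / agent$latency_mean_s)
      ev[[length(ev) + 1]] <- data.frame(time_s = onsets[i] + lat,
                                         event = "poke", detail = draw)
      if (draw == stimulus_port_map()[[stim[i]]] && lat <= 10) {
        ev[[length(ev) + 1]] <- data.frame(time_s = onsets[i] + lat,
                                           event = "reward", detail = draw)
      }
    }
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  out <- behavior_session(events)
  attr(out, "truth") <- data.frame(trial = seq_len(n_trials),
                                   stimulus = stim, onset_s = onsets)
  out
}

simulate_reversal <- function(config, agent, n_trials) {
  policy <- agent$policy
  stopifnot(policy %in% c("perfect", "chance", "wsls", "perseverative"))
  alpha <- 1 - exp(-1 / 12)
  good <- sample(c("left", "right"), 1)
  ema <- 0.5
  pending <- NA_integer_
  port <- character(n_trials)
  rewarded <- logical(n_trials)
  correct <- logical(n_trials)
  good_port <- character(n_trials)
  ema_trace <- numeric(n_trials)
  boundaries <- integer(0)
  prev_port <- sample(c("left", "right"), 1)
  prev_rew <- FALSE
  for (t in seq_len(n_trials)) {
    ## a scheduled reversal takes effect before trial t
    if (!is.na(pending) && t == pending) {
      good <- setdiff(c("left", "right"), good)
      boundaries <- c(boundaries, t)
      pending <- NA_integer_
    }
    choice <- switch(policy,
      perfect = good,
      chance = sample(c("left", "right"), 1),
      wsls = if (prev_rew) prev_port else setdiff(c("left", "right"), prev_port),
      perseverative = if (runif(1) < 0.9) prev_port
                      else setdiff(c("left", "right"), prev_port)
    )
    p_rew <- if (choice == good) config$reward_p_good else config$reward_p_bad
    rew <- runif(1) < p_rew
    corr <- choice == good
    ema <- ema + (as.numeric(corr) - ema) * alpha
    if (is.na(pending) && ema > 0.8) {
      pending <- t + sample(5:10, 1)
    }
    port[t] <- choice; rewarded[t] <- rew; correct[t] <- corr
    good_port[t] <- good; ema_trace[t] <- ema
    prev_port <- choice; prev_rew <- rew
  }
  block_id <- findInterval(seq_len(n_trials), boundaries) + 1L
  structure(list(
    choices = data.frame(trial = seq_len(n_trials), port = port,
                         good_port = good_port, rewarded = rewarded,
                         correct = correct, block_id = block_id),
    ema_trace = ema_trace,
    boundaries = boundaries
  ), class = "reversal_session")
}

#' @export
print.reversal_session <- function(x, ...) {
  cat("<reversal_session> ", nrow(x$choices), " trials, ",
      length(x$boundaries), " reversals, final EMA ",
      round(tail(x$ema_trace, 1), 3), "\n", sep = "")
  invisible(x)
}
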