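session_from <- function(...) behavior_session(data.frame(...))

one_trial <- function(stim, poke_port = NULL, poke_t = 2) {
  ev <- data.frame(time_s = 100, event = "stimulus_onset", detail = stim)
  if (!is.null(poke_port)) {
    ev <- rbind(ev, data.frame(time_s = 100 + poke_t, event = "poke",
                               detail = poke_port))
  }
  behavior_session(ev)
}

outcome_of <- function(tab, stim) {
  unlist(tab[tab$stimulus == stim,
             c("n_hit", "n_miss", "n_false_alarm", "n_correct_rejection")])
}

test_that("trial outcomes follow the first-poke-within-10-s rule", {
  # auditory trial, first poke left at 2 s -> hit(A), CR(V), CR(AV)
  tab <- classify_trials(one_trial("A", "left"))
  expect_equal(unname(outcome_of(tab, "A")), c(1, 0, 0, 0))
  expect_equal(unname(outcome_of(tab, "V")), c(0, 0, 0, 1))
  expect_equal(unname(outcome_of(tab, "AV")), c(0, 0, 0, 1))

  # auditory trial, first poke right -> miss(A), FA(V), CR(AV)
  tab2 <- classify_trials(one_trial("A", "right"))
  expect_equal(unname(outcome_of(tab2, "A")), c(0, 1, 0, 0))
  expect_equal(unname(outcome_of(tab2, "V")), c(0, 0, 1, 0))
  expect_equal(unname(outcome_of(tab2, "AV")), c(0, 0, 0, 1))

  # no poke within 10 s -> miss for the present stimulus, CRs otherwise
  tab3 <- classify_trials(one_trial("V", "right", poke_t = 11))
  expect_equal(unname(outcome_of(tab3, "V")), c(0, 1, 0, 0))
  expect_equal(unname(outcome_of(tab3, "A")), c(0, 0, 0, 1))

  # non-task port: miss for present, CR for absent
  tab4 <- classify_trials(one_trial("AV", "other"))
  expect_equal(unname(outcome_of(tab4, "AV")), c(0, 1, 0, 0))
  expect_equal(unname(outcome_of(tab4, "A")), c(0, 0, 0, 1))

  # pre-stimulus pokes are ignored with a log message
  s <- session_from(time_s = c(5, 100, 102),
                    event = c("poke", "stimulus_onset", "poke"),
                    detail = c("center", "A", "left"))
  expect_message(tab5 <- classify_trials(s), "ignored")
  expect_equal(unname(outcome_of(tab5, "A")), c(1, 0, 0, 0))
})

test_that("rates implement the hit and false-alarm formulas", {
  tab <- classify_trials(one_trial("A", "left"))
  tab$n_hit <- c(8, 0, 0)
  tab$n_miss <- c(2, 0, 0)
  tab$n_false_alarm <- c(0, 0, 0)
  tab$n_correct_rejection <- c(0, 20, 0)
  r <- rates(tab)
  expect_equal(r$HR[r$stimulus == "A"], 0.8)
  expect_equal(r$FR[r$stimulus == "V"], 0)
  expect_true(is.na(r$FR[r$stimulus == "A"]))  # zero denominator -> absent
})

test_that("outcome marginals always equal present/absent trial counts", {
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed)
    sess <- simulate_behavior_session(cfg, agent_rates(0.6, 0.15),
                                      "multimodal")
    truth <- attr(sess, "truth")
    tab <- classify_trials(sess)
    for (s in c("A", "V", "AV")) {
      present <- sum(truth$stimulus == s)
      row <- tab[tab$stimulus == s, ]
      expect_equal(row$n_hit + row$n_miss, present)
      expect_equal(row$n_false_alarm + row$n_correct_rejection,
                   nrow(truth) - present)
    }
  }
})

test_that("d-prime follows the normal-quantile formula with correction", {
  expect_equal(dprime(0.5, 0.5), 0)
  expect_equal(dprime(0.3, 0.3), 0)
  expect_equal(dprime(0.8413, 0.1587), 2, tolerance = 1e-3)
  # antisymmetry
  expect_equal(dprime(0.9, 0.2), -dprime(0.2, 0.9))
  # extreme-rate correction: 0 -> 1/(2N), 1 -> 1 - 1/(2N)
  expect_equal(dprime(1, 0, n_signal = 10, n_noise = 20),
               qnorm(1 - 1 / 20) - qnorm(1 / 40))
  expect_error(dprime(1, 0.2), "trial counts")
  expect_true(is.na(dprime(NA, 0.2)))
})

test_that("poke latencies are split by outcome and recount correctly", {
  s <- session_from(
    time_s = c(100, 102.5, 300, 301.2, 500),
    event = c("stimulus_onset", "poke", "stimulus_onset", "poke",
              "stimulus_onset"),
    detail = c("A", "left", "V", "center", "AV"))
  lat <- poke_latencies(s)
  expect_equal(nrow(lat), 2)  # the no-poke trial contributes nothing
  expect_equal(lat$latency_s[lat$stimulus == "A"], 2.5)
  expect_equal(lat$outcome, c("hit", "miss"))
  m <- attr(lat, "means")
  expect_equal(m$latency_s[m$stimulus == "A" & m$outcome == "hit"], 2.5)
})

test_that("hit percentages report the 33% chance reference", {
  tab <- classify_trials(one_trial("A", "left"))
  ph <- percent_hits(tab)
  expect_equal(ph$chance_percent, rep(100 / 3, 3))
  expect_equal(ph$percent_hit[ph$stimulus == "A"], 100)
  sess <- simulate_behavior_session(sim_config(seed = 61), agent_absent(),
                                    "multimodal")
  ph0 <- percent_hits(classify_trials(sess))
  expect_true(all(ph0$percent_hit == 0))
})

test_that("EMA equals the recursion oracle and stays in [0, 1]", {
  set.seed(71)
  for (i in 1:10) {
    x <- rbinom(20, 1, runif(1))
    expect_equal(ema_performance(x), ema_oracle(x), tolerance = 1e-14)
  }
  up <- ema_performance(rep(1, 200))
  expect_true(all(diff(up) > 0))
  expect_lt(abs(tail(up, 1) - 1), 1e-6)
  down <- ema_performance(rep(0, 200))
  expect_true(all(diff(down) < 0))
  expect_true(all(up >= 0 & up <= 1 & down >= 0 & down <= 1))
  expect_length(ema_performance(numeric(0)), 0)
})

test_that("reversal engine triggers 5-10 trials after threshold crossings", {
  up <- ema_performance(rep(1, 40))
  crossing <- which(up > 0.8)[1]
  for (seed in 1:10) {
    b <- reversal_engine(up, seed = seed)
    expect_true(b[1] - crossing >= 5 && b[1] - crossing <= 10)
  }
  expect_identical(reversal_engine(up, seed = 3), reversal_engine(up, seed = 3))
  # chance agent: EMA hovers near 0.5, never crosses
  flat <- ema_performance(rbinom(200, 1, 0.5))
  expect_length(reversal_engine(flat, seed = 1), 0)
})

test_that("simulated reversal sessions respect the trigger rule", {
  rv <- simulate_behavior_session(sim_config(seed = 81), list(policy = "perfect"),
                                  "reversal", n_trials = 200)
  expect_equal(rv$ema_trace, ema_oracle(rv$choices$correct), tolerance = 1e-12)
  first_cross <- which(rv$ema_trace > 0.8)[1]
  expect_true(rv$boundaries[1] - first_cross >= 5 &&
                rv$boundaries[1] - first_cross <= 10)
  expect_true(all(diff(rv$boundaries) >= 5 & diff(rv$boundaries) <= 10))
  # good port flips at each boundary
  flips <- which(diff(as.numeric(factor(rv$choices$good_port))) != 0) + 1L
  expect_identical(flips, as.integer(rv$boundaries))
})

test_that("transition alignment averages correctness around boundaries", {
  rv <- simulate_behavior_session(sim_config(seed = 82), list(policy = "perfect"),
                                  "reversal", n_trials = 200)
  al <- transition_alignment(rv$choices, rv$boundaries)
  expect_true(all(al$p_high_port[!is.na(al$p_high_port)] == 1))

  ch <- simulate_behavior_session(sim_config(seed = 83), list(policy = "chance"),
                                  "reversal", n_trials = 400)
  # chance agents rarely trigger reversals; align around synthetic boundaries
  al_ch <- transition_alignment(ch$choices, seq(30, 390, by = 30))
  vals <- al_ch$p_high_port
  expect_true(all(vals >= 0 & vals <= 1))
  expect_lt(abs(mean(vals) - 0.5), 0.15)

  none <- transition_alignment(rv$choices, integer(0))
  expect_true(all(is.na(none$p_high_port)))
})

test_that("lagged choice regression separates named policies", {
  wsls <- simulate_behavior_session(sim_config(seed = 84), list(policy = "wsls"),
                                    "reversal", n_trials = 400)
  fit_w <- suppressWarnings(lagged_choice_model(wsls$choices))
  co_w <- abs(fit_w$coefficients)
  expect_true(fit_w$separation)
  expect_gt(co_w["interaction"], 5)
  expect_gt(co_w["interaction"], 10 * co_w["prev_choice"] + 1e-9)

  pers <- simulate_behavior_session(sim_config(seed = 85),
                                    list(policy = "perseverative"),
                                    "reversal", n_trials = 400)
  fit_p <- suppressWarnings(lagged_choice_model(pers$choices))
  expect_gt(abs(fit_p$coefficients["prev_choice"]),
            abs(fit_p$coefficients["interaction"]))

  rnd <- simulate_behavior_session(sim_config(seed = 86), list(policy = "chance"),
                                   "reversal", n_trials = 2000)
  fit_r <- lagged_choice_model(rnd$choices)
  expect_true(all(abs(fit_r$coefficients) < 0.2))
  expect_false(fit_r$separation)

  expect_error(lagged_choice_model(rnd$choices[1:30, ]), ">= 50")
})
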