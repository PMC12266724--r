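test_that("sweep averaging is the pointwise mean", {
  one <- matrix(rep(c(1, 2, 3), each = 10), nrow = 10)
  expect_equal(average_sweeps(one), c(1, 2, 3))
  sym <- rbind(rep(1, 5), rep(-1, 5))
  expect_equal(average_sweeps(sym), rep(0, 5))
  set.seed(1)
  m <- matrix(rnorm(30), nrow = 3)
  expect_equal(average_sweeps(m), (m[1, ] + m[2, ] + m[3, ]) / 3)
})

test_that("response magnitude is the post-minus-pre window integral", {
  rate <- 10000
  n <- round(0.12 * rate)
  t_s <- (seq_len(n) - 1) / rate
  flat <- rep(2, n)
  expect_equal(response_magnitude(flat, rate, 0.05, 0.054), 0)

  # 1 mV over the whole 30 ms post window, zero elsewhere -> 0.03 mV s
  rect <- ifelse(t_s >= 0.054 & t_s <= 0.084, 1, 0)
  expect_equal(response_magnitude(rect, rate, 0.05, 0.054), 0.03,
               tolerance = 1e-9)

  # EPSP kernel vs analytic integral of the exponential over the window
  tau <- 0.02
  t0 <- 0.055
  kern <- ifelse(t_s >= t0, 3 * exp(-(t_s - t0) / tau), 0)
  analytic <- 3 * tau * (1 - exp(-(0.084 - t0) / tau))
  got <- response_magnitude(kern, rate, 0.05, 0.054)
  expect_equal(got, analytic, tolerance = 0.01)

  expect_error(response_magnitude(flat, rate, 0.01, 0.054), "bounds")
})

test_that("SD-rule significance uses 3 SD in current clamp, 5 in voltage", {
  ss <- deflection_sweeps(defl_start_s = 0.055, defl_amp = 0.4,
                          noise_sd = 0.1, seed = 3)
  mt <- average_sweeps(ss)
  # baseline SD of the averaged trace sits near 0.1/sqrt(10); scale the
  # deflection to 4 baseline SDs for the threshold contrast
  bl_idx <- sensint:::window_idx(length(mt), ss$rate, 0.02, 0.05)
  blsd <- sd(mt[bl_idx])
  mt4 <- mt
  mt4[(0.055 * ss$rate + 1):(0.057 * ss$rate)] <-
    mean(mt[bl_idx]) + 4 * blsd
  expect_true(significance_by_sd(mt4, ss$rate, "current", 0.05))
  expect_false(significance_by_sd(mt4, ss$rate, "voltage", 0.05))
  flat <- rep(0.5, length(mt))
  expect_false(significance_by_sd(flat, ss$rate, "current", 0.05))
})

test_that("Mann-Whitney p matches exhaustive enumeration at small n", {
  res <- significance_by_test(c(1, 2, 3), c(10, 11, 12), alpha = 0.10)
  expect_equal(res$p, 0.1)
  expect_equal(res$p, mw_enumeration_p(c(1, 2, 3), c(10, 11, 12)))
  expect_false(res$significant)

  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(4)
    y <- rnorm(5)
    expect_equal(significance_by_test(x, y)$p, mw_enumeration_p(x, y),
                 tolerance = 1e-12)
  }
  same <- significance_by_test(1:6, 1:6)
  expect_gt(same$p, 0.9)
  expect_error(significance_by_test(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("null Mann-Whitney rejection rate sits near the nominal level", {
  set.seed(42)
  p <- replicate(1000, sensint:::mw_p(rnorm(10), rnorm(10)))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("latency classification applies the 3 and 12 ms gates", {
  mk <- function(lat_ms) {
    ss <- deflection_sweeps(defl_start_s = 0.05 + lat_ms / 1000,
                            defl_len_s = 0.004, defl_amp = 3,
                            noise_sd = 0.05, seed = 8)
    classify_latency(average_sweeps(ss), ss$rate, "current", 0.05)
  }
  r2 <- mk(2)
  expect_equal(r2$classification, "direct_opsin")
  expect_lt(r2$latency_ms, 3)
  r5 <- mk(5)
  expect_equal(r5$classification, "monosynaptic")
  expect_true(r5$latency_ms >= 3 && r5$latency_ms <= 12)
  r20 <- mk(20)
  expect_equal(r20$classification, "polysynaptic_or_late")
  flat <- classify_latency(rep(0, 1200), 10000, "current", 0.05)
  expect_equal(flat$classification, "none")
  expect_true(is.na(flat$latency_ms))
})

test_that("integration probabilities reproduce forced arithmetic", {
  pr <- integration_probabilities(20, 14, 14, 4)
  expect_equal(pr$p_expected, 0.49)
  expect_equal(pr$p_measured, 0.20)
  expect_equal(pr$ratio, 0.20 / 0.49)

  sat <- integration_probabilities(10, 10, 10, 10)
  expect_equal(sat$p_expected, 1)
  expect_equal(sat$ratio, 1)

  none <- integration_probabilities(10, 0, 0, 0)
  expect_true(is.na(none$ratio))
})

test_that("expected integration equals a recount oracle on random calls", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    r1 <- runif(n) < runif(1)
    r2 <- runif(n) < runif(1)
    tab <- integration_table(r1, r2)
    # counts recomputable from unit-level calls
    expect_equal(tab$n_input1_only + tab$n_input2_only + tab$n_both +
                   tab$n_neither, n)
    ei <- expected_integration(tab, n_boot = 0)
    p1 <- mean(r1)
    p2 <- mean(r2)
    expect_equal(ei$p_expected, p1 * p2, tolerance = 1e-12)
    expect_equal(ei$p_measured, mean(r1 & r2), tolerance = 1e-12)
    if (p1 * p2 > 0) {
      expect_equal(ei$ratio, mean(r1 & r2) / (p1 * p2), tolerance = 1e-12)
    }
  }
})

test_that("bootstrap ratio uncertainty is seeded and plausible", {
  tab <- integration_table(c(rep(TRUE, 12), rep(FALSE, 8)),
                           c(rep(TRUE, 6), rep(FALSE, 10), rep(TRUE, 4)))
  a <- expected_integration(tab, n_boot = 500, seed = 3)
  b <- expected_integration(tab, n_boot = 500, seed = 3)
  expect_identical(a$ratio_sd, b$ratio_sd)
  expect_gt(a$ratio_sd, 0)
})

test_that("dual-color bookkeeping pairs channels and applies exclusions", {
  cfg <- sim_config(seed = 12, epsp_amplitude = 2, ephys_noise_sd = 0.2)
  both <- simulate_opto_sweeps(cfg, connectivity = c(1L, 2L))
  b <- dual_color_bookkeeping(both)
  expect_true(b$responds_input1 && b$responds_input2 && b$responds_both)

  only1 <- simulate_opto_sweeps(cfg, connectivity = 1L)
  b1 <- dual_color_bookkeeping(only1)
  expect_true(b1$responds_input1)
  expect_false(b1$responds_input2)
  expect_false(b1$responds_both)

  miss <- dual_color_bookkeeping(both["input1"])
  expect_true(miss$excluded)
  expect_match(miss$exclude_reason, "missing channel: input2")

  sim_ss <- both$input1
  sim_ss$input_channel <- "simultaneous"
  flagged <- dual_color_bookkeeping(c(both, list(sim = sim_ss)))
  expect_true(flagged$simultaneous_present)
  expect_false(flagged$excluded)

  fast <- simulate_opto_sweeps(sim_config(seed = 13, epsp_latency_ms = 2,
                                          epsp_amplitude = 2,
                                          ephys_noise_sd = 0.2),
                               connectivity = c(1L, 2L))
  bf <- dual_color_bookkeeping(fast)
  expect_true(bf$excluded)
  expect_match(bf$exclude_reason, "direct opsin")
})

test_that("raising EPSP amplitude never decreases the responsive fraction", {
  amps <- c(0, 0.25, 0.5, 1, 2)
  frac <- vapply(amps, function(a) {
    calls <- vapply(1:20, function(i) {
      cfg <- sim_config(seed = 100 + i, epsp_amplitude = a,
                        ephys_noise_sd = 0.5)
      ss <- simulate_opto_sweeps(cfg, connectivity = 1L)
      b <- dual_color_bookkeeping(ss)
      isTRUE(b$responds_input1)
    }, logical(1))
    mean(calls)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_equal(frac[1], 0)
  expect_equal(frac[length(frac)], 1)
})
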