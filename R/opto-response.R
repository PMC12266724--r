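## Evoked-response detection and input-integration statistics for
## trial-organized patch-clamp sweeps.

#' Average sweeps across trials
#'
#' @param sweeps A [sweep_set()] (or a trials x samples matrix).
#' @return Numeric vector: the pointwise mean trace.
#' @export
average_sweeps <- function(sweeps) {
  m <- if (inherits(sweeps, "sweep_set")) sweeps$sweeps else sweeps
  if (!is.matrix(m) || nrow(m) < 1) stop("need >= 1 sweep", call. = FALSE)
  colMeans(m)
}

## sample indices whose times fall in [a, b]; errors if the window is not
## fully covered by the trace
window_idx <- function(n, rate, a, b) {
  t_s <- (seq_len(n) - 1) / rate
  if (a < -1e-9 || b > t_s[n] + 1e-9) {
    stop("analysis window [", a, ", ", b, "] s exceeds trace bounds",
         call. = FALSE)
  }
  which(t_s >= a - 1e-9 & t_s <= b + 1e-9)
}

#' Evoked response magnitude
#'
#' Difference of the trapezoidal integrals of the 30 ms post-stimulus window
#' (starting at stimulus offset) and the 30 ms pre-stimulus window (ending at
#' stimulus onset).
#'
#' @param mean_trace Numeric trace (typically from [average_sweeps()]).
#' @param rate Sampling rate, Hz.
#' @param stim_onset,stim_offset Stimulus onset/offset, seconds.
#' @param window_s Integration window length, seconds (30 ms).
#' @return Magnitude in signal x seconds (e.g. mV s) relative to baseline.
#' @export
response_magnitude <- function(mean_trace, rate, stim_onset, stim_offset,
                               window_s = 0.03) {
  n <- length(mean_trace)
  t_s <- (seq_len(n) - 1) / rate
  pre <- window_idx(n, rate, stim_onset - window_s, stim_onset)
  post <- window_idx(n, rate, stim_offset, stim_offset + window_s)
  pracma::trapz(t_s[post], mean_trace[post]) -
    pracma::trapz(t_s[pre], mean_trace[pre])
}

## first time (s, relative to stim_onset) at which |trace - mu| > thr is
## sustained for >= sustain samples; NA if never
first_crossing_s <- function(trace, rate, stim_onset, mu, thr,
                             sustain_ms = 1) {
  n <- length(trace)
  t_s <- (seq_len(n) - 1) / rate
  post <- which(t_s >= stim_onset)
  dev <- abs(trace[post] - mu) > thr
  k <- max(1L, round(sustain_ms / 1000 * rate))
  if (length(dev) < k) return(NA_real_)
  runs <- rle(dev)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- runs$values & runs$lengths >= k
  if (!any(ok)) return(NA_real_)
  t_s[post[starts[which(ok)[1]]]] - stim_onset
}

#' SD-threshold response significance
#'
#' A response is significant when the trial-averaged trace deviates from the
#' baseline mean by more than k baseline standard deviations — k = 3 in
#' current clamp and k = 5 in voltage clamp — for at least `sustain_ms`
#' milliseconds after stimulus onset. The baseline is the 30 ms pre-onset
#' window by default (`baseline_window = "pre_window"`); the full pre-stimulus
#' sweep is available via `"full"`.
#'
#' @param mean_trace Numeric trial-averaged trace.
#' @param rate Sampling rate, Hz.
#' @param clamp_mode `"current"` (k = 3) or `"voltage"` (k = 5).
#' @param stim_onset Stimulus onset, seconds.
#' @param baseline_window `"pre_window"` (30 ms before onset) or `"full"`
#'   (everything before onset).
#' @param sustain_ms Minimum duration the deviation must last; 0 gives the
#'   literal single-sample threshold rule.
#' @return Logical.
#' @export
significance_by_sd <- function(mean_trace, rate,
                               clamp_mode = c("current", "voltage"),
                               stim_onset,
                               baseline_window = c("pre_window", "full"),
                               sustain_ms = 1) {
  clamp_mode <- match.arg(clamp_mode)
  baseline_window <- match.arg(baseline_window)
  k <- if (clamp_mode == "current") 3 else 5
  bl <- baseline_stats(mean_trace, rate, stim_onset, baseline_window)
  !is.na(first_crossing_s(mean_trace, rate, stim_onset, bl$mu, k * bl$sd,
                          sustain_ms))
}

baseline_stats <- function(trace, rate, stim_onset, baseline_window) {
  n <- length(trace)
  idx <- if (baseline_window == "pre_window") {
    window_idx(n, rate, stim_onset - 0.03, stim_onset)
  } else {
    window_idx(n, rate, 0, stim_onset)
  }
  list(mu = mean(trace[idx]), sd = stats::sd(trace[idx]))
}

#' Mann–Whitney response test on per-trial window summaries
#'
#' Two-sided Mann–Whitney U test comparing per-trial pre-stimulus and
#' post-stimulus summary values (window integrals). Exact when the combined
#' sample size is at most 12 and tie-free; normal approximation with tie and
#' continuity correction otherwise. Family-wise discovery control
#' (Benjamini–Hochberg across all cells of a batch) is applied by
#' [analyze_opto_cells()]; the `significant` flag here compares the raw p to
#' `alpha`.
#'
#' @param per_trial_pre,per_trial_post Numeric vectors, >= 3 values each.
#' @param alpha Significance level (0.10 in the mapping analysis).
#' @return List with `p` and `significant`.
#' @export
significance_by_test <- function(per_trial_pre, per_trial_post, alpha = 0.10) {
  if (length(per_trial_pre) < 3 || length(per_trial_post) < 3) {
    stop("need >= 3 trials per group", call. = FALSE)
  }
  p <- mw_p(per_trial_pre, per_trial_post)
  list(p = p, significant = p < alpha)
}

mw_p <- function(x, y) {
  exact <- (length(x) + length(y)) <= 12 && !any(duplicated(c(x, y)))
  suppressWarnings(stats::wilcox.test(x, y, exact = exact)$p.value)
}

#' Latency-based response classification
#'
#' Latency is the time from stimulus onset to the first sustained crossing of
#' baseline mean +/- k SD on the trial-averaged trace. Latencies under 3 ms
#' indicate direct opsin expression in the recorded cell (excluded from
#' connectivity analysis), 3–12 ms a monosynaptic connection, and longer a
#' polysynaptic or late response.
#'
#' @inheritParams significance_by_sd
#' @return List with `classification` (`"direct_opsin"`, `"monosynaptic"`,
#'   `"polysynaptic_or_late"` or `"none"`) and `latency_ms` (`NA` when no
#'   crossing).
#' @export
classify_latency <- function(mean_trace, rate,
                             clamp_mode = c("current", "voltage"),
                             stim_onset,
                             baseline_window = c("pre_window", "full"),
                             sustain_ms = 1) {
  clamp_mode <- match.arg(clamp_mode)
  baseline_window <- match.arg(baseline_window)
  k <- if (clamp_mode == "current") 3 else 5
  bl <- baseline_stats(mean_trace, rate, stim_onset, baseline_window)
  lat_s <- first_crossing_s(mean_trace, rate, stim_onset, bl$mu, k * bl$sd,
                            sustain_ms)
  if (is.na(lat_s)) {
    return(list(classification = "none", latency_ms = NA_real_))
  }
  lat_ms <- lat_s * 1000
  cls <- if (lat_ms < 3) "direct_opsin"
         else if (lat_ms <= 12) "monosynaptic"
         else "polysynaptic_or_late"
  list(classification = cls, latency_ms = lat_ms)
}

#' Full response call for one sweep set
#'
#' Combines [average_sweeps()], [response_magnitude()], the SD-threshold rule,
#' the per-trial Mann–Whitney test and the latency classification into one
#' record for a (cell, input channel) pair.
#'
#' @param ss A [sweep_set()].
#' @param sustain_ms Passed to the threshold rules.
#' @param baseline_window Passed to the threshold rules.
#' @param window_s Integration window (30 ms).
#' @return A `response_call` list: `magnitude`, `significant_sd`, `p`,
#'   `latency_ms`, `classification`, `input_channel`.
#' @export
response_call <- function(ss, sustain_ms = 1,
                          baseline_window = c("pre_window", "full"),
                          window_s = 0.03) {
  stopifnot(inherits(ss, "sweep_set"))
  baseline_window <- match.arg(baseline_window)
  mt <- average_sweeps(ss)
  mag <- response_magnitude(mt, ss$rate, ss$stim_onset, ss$stim_offset,
                            window_s)
  sig_sd <- significance_by_sd(mt, ss$rate, ss$clamp_mode, ss$stim_onset,
                               baseline_window, sustain_ms)
  lat <- classify_latency(mt, ss$rate, ss$clamp_mode, ss$stim_onset,
                          baseline_window, sustain_ms)
  n <- ncol(ss$sweeps)
  t_s <- (seq_len(n) - 1) / ss$rate
  pre_i <- window_idx(n, ss$rate, ss$stim_onset - window_s, ss$stim_onset)
  post_i <- window_idx(n, ss$rate, ss$stim_offset, ss$stim_offset + window_s)
  pre <- apply(ss$sweeps[, pre_i, drop = FALSE], 1,
               function(r) pracma::trapz(t_s[pre_i], r))
  post <- apply(ss$sweeps[, post_i, drop = FALSE], 1,
                function(r) pracma::trapz(t_s[post_i], r))
  p <- if (nrow(ss$sweeps) >= 3) mw_p(pre, post) else NA_real_
  structure(list(magnitude = mag, significant_sd = sig_sd, p = p,
                 latency_ms = lat$latency_ms,
                 classification = lat$classification,
                 input_channel = ss$input_channel),
            class = "response_call")
}

#' Per-cell dual-color input bookkeeping
#'
#' Each cell is probed separately on two opsin channels (595 nm/Chrimson for
#' input 1, then a desensitizing 595 nm pulse followed by 470 nm/Chronos for
#' input 2). This pairs the per-channel response calls into a per-cell
#' connectivity record. Simultaneous-pulse sweep sets are flagged and excluded
#' from magnitude analysis; cells missing a channel are excluded with a
#' reason; cells with a sub-3 ms (direct opsin) latency on either channel are
#' excluded from integration counts.
#'
#' @param cell_sweeps List of [sweep_set()] objects for one cell, tagged by
#'   `input_channel` (`"input1"`, `"input2"`, optionally `"simultaneous"`).
#' @param ... Passed to [response_call()].
#' @return List with `responds_input1`, `responds_input2`, `responds_both`,
#'   `excluded`, `exclude_reason`, `calls` (per-channel `response_call`s) and
#'   `simultaneous_present`.
#' @export
dual_color_bookkeeping <- function(cell_sweeps, ...) {
  channels <- vapply(cell_sweeps, function(s) s$input_channel, character(1))
  simultaneous <- any(channels == "simultaneous")
  out <- list(responds_input1 = NA, responds_input2 = NA, responds_both = NA,
              excluded = FALSE, exclude_reason = NA_character_,
              calls = NULL, simultaneous_present = simultaneous)
  if (!all(c("input1", "input2") %in% channels)) {
    out$excluded <- TRUE
    out$exclude_reason <- paste0(
      "missing channel: ",
      paste(setdiff(c("input1", "input2"), channels), collapse = ", "))
    return(out)
  }
  c1 <- response_call(cell_sweeps[[match("input1", channels)]], ...)
  c2 <- response_call(cell_sweeps[[match("input2", channels)]], ...)
  out$calls <- list(input1 = c1, input2 = c2)
  if (c1$classification == "direct_opsin" ||
      c2$classification == "direct_opsin") {
    out$excluded <- TRUE
    out$exclude_reason <- "direct opsin expression (latency < 3 ms)"
    return(out)
  }
  out$responds_input1 <- isTRUE(c1$significant_sd) && c1$classification != "none"
  out$responds_input2 <- isTRUE(c2$significant_sd) && c2$classification != "none"
  out$responds_both <- out$responds_input1 && out$responds_input2
  out
}

#' Build an integration count table from per-cell calls
#'
#' @param responds_input1,responds_input2 Logical vectors over cells (already
#'   excluding direct-opsin and incomplete cells).
#' @return An `integration_table`: list of counts `n_total`,
#'   `n_input1_only`, `n_input2_only`, `n_both`, `n_neither`.
#' @export
integration_table <- function(responds_input1, responds_input2) {
  stopifnot(length(responds_input1) == length(responds_input2))
  r1 <- as.logical(responds_input1); r2 <- as.logical(responds_input2)
  structure(list(
    n_total = length(r1),
    n_input1_only = sum(r1 & !r2),
    n_input2_only = sum(!r1 & r2),
    n_both = sum(r1 & r2),
    n_neither = sum(!r1 & !r2)
  ), class = "integration_table")
}

#' @export
print.integration_table <- function(x, ...) {
  cat("<integration_table> n =", x$n_total,
      "| input1 only:", x$n_input1_only,
      "input2 only:", x$n_input2_only,
      "both:", x$n_both, "neither:", x$n_neither, "\n")
  invisible(x)
}

#' Integration probabilities from marginal response counts
#'
#' Core arithmetic of the integration statistic: given the number of cells
#' responding to each input (including dual responders) and the number
#' responding to both, returns the marginal response probabilities, the
#' expected dual-response probability under independence (their product), the
#' measured dual-response probability, and the measured/expected ratio.
#'
#' @param n_total Cells tested with both inputs (> 0).
#' @param n_input1,n_input2 Cells responding to each input (dual responders
#'   counted in both).
#' @param n_both Cells responding to both inputs.
#' @return List with `p_input1`, `p_input2`, `p_expected`, `p_measured`,
#'   `ratio`.
#' @export
#' @examples
#' # 20 cells, 14 responding to each input, 4 to both:
#' integration_probabilities(20, 14, 14, 4)  # ratio ~ 0.408
integration_probabilities <- function(n_total, n_input1, n_input2, n_both) {
  if (n_total <= 0) stop("n_total must be > 0", call. = FALSE)
  stopifnot(n_input1 >= n_both, n_input2 >= n_both, n_both >= 0)
  p1 <- n_input1 / n_total
  p2 <- n_input2 / n_total
  p_exp <- p1 * p2
  p_meas <- n_both / n_total
  if (p_exp == 0 && n_both > 0) {
    stop("ratio undefined: expected probability 0 with observed integration",
         call. = FALSE)
  }
  ratio <- if (p_exp == 0) NA_real_ else p_meas / p_exp
  list(p_input1 = p1, p_input2 = p2, p_expected = p_exp,
       p_measured = p_meas, ratio = ratio)
}

#' Expected vs measured input integration
#'
#' Under independence of the two cortical inputs, the expected probability
#' that a cell responds to both is the product of the marginal response
#' probabilities: `p_expected = p(input1) * p(input2)` with
#' `p(input_i) = (n_i_only + n_both) / n_total`. The measured probability is
#' `n_both / n_total`; their ratio quantifies over- (> 1) or under- (< 1)
#' representation of integrating cells. Uncertainty on the ratio is a seeded
#' cell-resampling bootstrap SD.
#'
#' @param table An [integration_table()].
#' @param n_boot Bootstrap draws for the ratio SD (0 to skip).
#' @param seed Seed for the bootstrap.
#' @return List with `p_input1`, `p_input2`, `p_expected`, `p_measured`,
#'   `ratio` (`NA` when `p_expected` is 0 and `n_both` is 0) and `ratio_sd`.
#' @export
#' @examples
#' tab <- integration_table(responds_input1 = c(rep(TRUE, 8), rep(FALSE, 12)),
#'                          responds_input2 = c(rep(TRUE, 4), rep(FALSE, 8),
#'                                              rep(TRUE, 4), rep(FALSE, 4)))
#' expected_integration(tab, n_boot = 0)
expected_integration <- function(table, n_boot = 10000, seed = 1L) {
  stopifnot(inherits(table, "integration_table"))
  n <- table$n_total
  pr <- integration_probabilities(
    n_total = n,
    n_input1 = table$n_input1_only + table$n_both,
    n_input2 = table$n_input2_only + table$n_both,
    n_both = table$n_both
  )
  p1 <- pr$p_input1; p2 <- pr$p_input2
  p_exp <- pr$p_expected; p_meas <- pr$p_measured
  ratio <- pr$ratio
  ratio_sd <- NA_real_
  if (n_boot > 0 && !is.na(ratio)) {
    cats <- rep(c("b", "r1", "r2", "no"),
                c(table$n_both, table$n_input1_only, table$n_input2_only,
                  table$n_neither))
    set.seed(seed)
    rb <- replicate(n_boot, {
      s <- sample(cats, n, replace = TRUE)
      nb <- sum(s == "b")
      q1 <- (sum(s == "r1") + nb) / n
      q2 <- (sum(s == "r2") + nb) / n
      if (q1 * q2 == 0) NA_real_ else (nb / n) / (q1 * q2)
    })
    ratio_sd <- stats::sd(rb, na.rm = TRUE)
  }
  list(p_input1 = p1, p_input2 = p2, p_expected = p_exp,
       p_measured = p_meas, ratio = ratio, ratio_sd = ratio_sd)
}

#' Batch analysis of dual-input mapping cells
#'
#' Runs [dual_color_bookkeeping()] over a batch of cells, applies
#' Benjamini–Hochberg FDR control at `alpha` to the Mann–Whitney p-values
#' across the whole batch (the default test family: all channels of all cells
#' in one dataset), and assembles the [integration_table()] and
#' [expected_integration()] report. A cell's final "responds" call on a
#' channel requires both the SD-threshold rule and a BH discovery.
#'
#' @param cells List of per-cell sweep-set lists (see
#'   [dual_color_bookkeeping()]).
#' @param alpha BH false-discovery level (0.10).
#' @param n_boot,boot_seed Bootstrap settings for [expected_integration()].
#' @param ... Passed to [response_call()].
#' @return List with `cells` (per-cell data frame), `table`, `integration`,
#'   `excluded` (data frame of excluded cells and reasons).
#' @export
analyze_opto_cells <- function(cells, alpha = 0.10, n_boot = 10000,
                               boot_seed = 1L, ...) {
  book <- lapply(cells, dual_color_bookkeeping, ...)
  kept <- !vapply(book, `[[`, logical(1), "excluded")
  p_mat <- t(vapply(book[kept], function(b) {
    c(b$calls$input1$p, b$calls$input2$p)
  }, numeric(2)))
  p_adj <- matrix(stats::p.adjust(p_mat, method = "BH"), ncol = 2)
  kept_idx <- which(kept)
  r1 <- r2 <- logical(length(kept_idx))
  for (j in seq_along(kept_idx)) {
    b <- book[[kept_idx[j]]]
    r1[j] <- b$responds_input1 && !is.na(p_adj[j, 1]) && p_adj[j, 1] <= alpha
    r2[j] <- b$responds_input2 && !is.na(p_adj[j, 2]) && p_adj[j, 2] <= alpha
  }
  tab <- integration_table(r1, r2)
  cells_df <- data.frame(
    cell = kept_idx,
    responds_input1 = r1, responds_input2 = r2,
    p_input1 = p_mat[, 1], p_input2 = p_mat[, 2],
    p_adj_input1 = p_adj[, 1], p_adj_input2 = p_adj[, 2],
    latency_input1_ms = vapply(book[kept], function(b) b$calls$input1$latency_ms,
                               numeric(1)),
    latency_input2_ms = vapply(book[kept], function(b) b$calls$input2$latency_ms,
                               numeric(1)),
    magnitude_input1 = vapply(book[kept], function(b) b$calls$input1$magnitude,
                              numeric(1)),
    magnitude_input2 = vapply(book[kept], function(b) b$calls$input2$magnitude,
                              numeric(1))
  )
  excluded <- data.frame(
    cell = which(!kept),
    reason = vapply(book[!kept], `[[`, character(1), "exclude_reason")
  )
  list(cells = cells_df, table = tab,
       integration = expected_integration(tab, n_boot = n_boot,
                                          seed = boot_seed),
       excluded = excluded)
}
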