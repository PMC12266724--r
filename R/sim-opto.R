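#' Construct a sweep set
#'
#' Trial-organized patch-clamp sweeps for one cell and one photostimulated
#' input channel.
#'
#' @param sweeps Trials x samples numeric matrix (mV in current clamp, pA in
#'   voltage clamp).
#' @param rate Sampling rate, Hz.
#' @param clamp_mode `"current"` or `"voltage"`; selects the downstream
#'   SD-threshold constant (3 vs 5).
#' @param stim_onset,stim_offset Photostimulus onset/offset, seconds, with
#'   `stim_onset < stim_offset` inside the sweep.
#' @param input_channel Label for the probed input (e.g. `"input1"` for the
#'   595 nm/Chrimson pathway, `"input2"` for the desensitized-470 nm/Chronos
#'   pathway, `"simultaneous"` for dual pulses).
#' @return A `sweep_set` object.
#' @export
sweep_set <- function(sweeps, rate, clamp_mode = c("current", "voltage"),
                      stim_onset, stim_offset, input_channel = "input1") {
  clamp_mode <- match.arg(clamp_mode)
  stopifnot(is.matrix(sweeps), rate > 0)
  dur <- ncol(sweeps) / rate
  if (!(stim_onset < stim_offset && stim_offset < dur)) {
    stop("need stim_onset < stim_offset < sweep end", call. = FALSE)
  }
  structure(list(sweeps = sweeps, rate = rate, clamp_mode = clamp_mode,
                 stim_onset = stim_onset, stim_offset = stim_offset,
                 input_channel = input_channel),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat("<sweep_set> ", nrow(x$sweeps), " sweeps x ", ncol(x$sweeps),
      " samples @ ", x$rate, " Hz, ", x$clamp_mode, " clamp, channel ",
      x$input_channel, "\n", sep = "")
  invisible(x)
}

#' Simulate dual-input optogenetic mapping sweeps for one cell
#'
#' Produces one [sweep_set()] per probed input channel. For inputs in
#' `connectivity` each sweep carries an EPSP-shaped deflection — instantaneous
#' rise at `stim_onset + epsp_latency_ms` followed by single-exponential decay
#' (`epsp_decay_ms`) — with uniform amplitude jitter of `epsp_jitter` around
#' `epsp_amplitude`. Unconnected inputs yield baseline noise only.
#'
#' @param config A [sim_config()]; `epsp_latency_ms` must be >= 0.
#' @param connectivity Integer subset of `c(1, 2)`: which cortical inputs are
#'   synaptically connected to the cell.
#' @param n_trials Sweeps per channel (10 in the mapping protocol).
#' @param clamp_mode `"current"` or `"voltage"`.
#' @return Named list of two `sweep_set` objects (`input1`, `input2`).
#' @export
#' @examples
#' ss <- simulate_opto_sweeps(sim_config(seed = 3), connectivity = c(1L, 2L))
#' sapply(ss, function(s) nrow(s$sweeps))
simulate_opto_sweeps <- function(config, connectivity = integer(0),
                                 n_trials = 10,
                                 clamp_mode = c("current", "voltage")) {
  clamp_mode <- match.arg(clamp_mode)
  stopifnot(n_trials >= 1, all(connectivity %in% c(1L, 2L)))
  set.seed(config$seed + 3L)
  rate <- config$sweep_rate
  n_samp <- round(config$sweep_duration_s * rate)
  t_s <- (seq_len(n_samp) - 1) / rate
  t0 <- config$opto_onset_s + config$epsp_latency_ms / 1000

  one_channel <- function(channel, connected) {
    sw <- matrix(rnorm(n_trials * n_samp, 0, config$ephys_noise_sd),
                 nrow = n_trials)
    if (connected && config$epsp_amplitude > 0) {
      kern <- ifelse(t_s >= t0,
                     exp(-(t_s - t0) * 1000 / config$epsp_decay_ms), 0)
      amp <- config$epsp_amplitude *
        runif(n_trials, 1 - config$epsp_jitter, 1 + config$epsp_jitter)
      sw <- sw + outer(amp, kern)
    }
    sweep_set(sw, rate = rate, clamp_mode = clamp_mode,
              stim_onset = config$opto_onset_s,
              stim_offset = config$opto_onset_s + config$opto_duration_s,
              input_channel = channel)
  }
  list(input1 = one_channel("input1", 1L %in% connectivity),
       input2 = one_channel("input2", 2L %in% connectivity))
}
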