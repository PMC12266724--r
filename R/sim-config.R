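#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators into one validated
#' object. Identical `(seed, config)` pairs yield bit-identical simulated data;
#' reproducibility is only guaranteed when `n_units` is also held fixed, since
#' each generator call consumes one seeded random stream.
#'
#' Defaults follow the acquisition conditions of the experiments the generators
#' emulate: 30 Hz imaging, 8–11 s inter-trial intervals over 120 trials, 500 ms
#' stimuli. Quantities the protocol does not fix (noise magnitudes, transient
#' amplitude and decay, spontaneous event rate) are exposed here with
#' field-realistic defaults and are not claims about real axons.
#'
#' @param seed Integer seed for the generator's random stream.
#' @param n_units Number of simulated units (axons or cells).
#' @param frame_rate Imaging frame rate, Hz.
#' @param iti_range Inter-trial interval range, seconds, `c(low, high)` with
#'   `low < high`.
#' @param n_trials Number of stimulus presentations per session.
#' @param stim_duration_s Sensory stimulus duration, seconds.
#' @param baseline Baseline fluorescence, arbitrary units (> 0 so that
#'   \eqn{\Delta F/F} is well defined).
#' @param noise_sd Per-frame Gaussian noise SD on fluorescence, same units as
#'   `baseline`.
#' @param transient_amplitude Peak amplitude of an evoked calcium transient,
#'   fluorescence units.
#' @param transient_decay Single-exponential decay time constant of a
#'   transient, seconds.
#' @param spontaneous_rate Rate of spontaneous (stimulus-independent)
#'   transients per unit, Hz; 0 disables them.
#' @param sweep_rate Electrophysiology sampling rate, Hz.
#' @param sweep_duration_s Length of one sweep, seconds.
#' @param opto_onset_s Photostimulus onset within a sweep, seconds.
#' @param opto_duration_s Photostimulus pulse duration, seconds (4 ms pulses).
#' @param epsp_latency_ms Synaptic latency from stimulus onset to response
#'   onset, milliseconds; must be >= 0.
#' @param epsp_amplitude EPSP/EPSC peak amplitude (mV in current clamp, pA in
#'   voltage clamp).
#' @param epsp_decay_ms EPSP decay time constant, milliseconds.
#' @param epsp_jitter Fractional trial-to-trial amplitude jitter (uniform in
#'   `[1 - j, 1 + j]`).
#' @param ephys_noise_sd Per-sample recording noise SD (mV or pA).
#' @param reward_p_good,reward_p_bad Reward probabilities of the good and bad
#'   port in the reversal task.
#' @param activity_bin_s Home-cage activity bin width, seconds.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [make_stimulus_schedule()], [simulate_axon_population()],
#'   [simulate_opto_sweeps()], [simulate_behavior_session()],
#'   [simulate_activity_series()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 42, n_units = 10, n_trials = 24)
#' cfg$iti_range
sim_config <- function(seed = 1L,
                       n_units = 50L,
                       frame_rate = 30,
                       iti_range = c(8, 11),
                       n_trials = 120L,
                       stim_duration_s = 0.5,
                       baseline = 1.0,
                       noise_sd = 0.1,
                       transient_amplitude = 0.5,
                       transient_decay = 0.5,
                       spontaneous_rate = 0,
                       sweep_rate = 10000,
                       sweep_duration_s = 0.12,
                       opto_onset_s = 0.05,
                       opto_duration_s = 0.004,
                       epsp_latency_ms = 5,
                       epsp_amplitude = 2,
                       epsp_decay_ms = 20,
                       epsp_jitter = 0.2,
                       ephys_noise_sd = 0.5,
                       reward_p_good = 0.85,
                       reward_p_bad = 0.15,
                       activity_bin_s = 60) {
  cfg <- list(
    seed = as.integer(seed), n_units = as.integer(n_units),
    frame_rate = frame_rate, iti_range = iti_range,
    n_trials = as.integer(n_trials), stim_duration_s = stim_duration_s,
    baseline = baseline, noise_sd = noise_sd,
    transient_amplitude = transient_amplitude,
    transient_decay = transient_decay, spontaneous_rate = spontaneous_rate,
    sweep_rate = sweep_rate, sweep_duration_s = sweep_duration_s,
    opto_onset_s = opto_onset_s, opto_duration_s = opto_duration_s,
    epsp_latency_ms = epsp_latency_ms, epsp_amplitude = epsp_amplitude,
    epsp_decay_ms = epsp_decay_ms, epsp_jitter = epsp_jitter,
    ephys_noise_sd = ephys_noise_sd,
    reward_p_good = reward_p_good, reward_p_bad = reward_p_bad,
    activity_bin_s = activity_bin_s
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$iti_range) == 2)
  if (!(cfg$iti_range[1] < cfg$iti_range[2])) {
    stop("iti_range must satisfy low < high", call. = FALSE)
  }
  for (f in c("frame_rate", "sweep_rate", "stim_duration_s", "baseline",
              "transient_decay", "epsp_decay_ms", "activity_bin_s")) {
    if (!(cfg[[f]] > 0)) stop(f, " must be > 0", call. = FALSE)
  }
  for (f in c("noise_sd", "spontaneous_rate", "ephys_noise_sd",
              "transient_amplitude", "epsp_amplitude")) {
    if (cfg[[f]] < 0) stop(f, " must be >= 0", call. = FALSE)
  }
  if (cfg$epsp_latency_ms < 0) {
    stop("epsp_latency_ms must be >= 0", call. = FALSE)
  }
  if (cfg$n_trials < 0 || cfg$n_units < 0) {
    stop("counts must be >= 0", call. = FALSE)
  }
  for (f in c("reward_p_good", "reward_p_bad")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, " units:", x$n_units, " trials:", x$n_trials, "\n")
  cat("  imaging:", x$frame_rate, "Hz, ITI", x$iti_range[1], "-", x$iti_range[2],
      "s, stim", x$stim_duration_s * 1000, "ms\n")
  cat("  ephys:", x$sweep_rate, "Hz sweeps,", x$epsp_latency_ms,
      "ms latency,", x$epsp_amplitude, "amplitude\n")
  invisible(x)
}
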