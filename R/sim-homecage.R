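#' Construct an activity series
#'
#' @param bins Data frame with columns `start_s`, `activity_index` (>= 0,
#'   arbitrary units) and `phase` (`"light"` or `"dark"`).
#' @param bin_width_s Uniform bin width, seconds.
#' @return An `activity_series` object.
#' @export
activity_series <- function(bins, bin_width_s) {
  stopifnot(all(c("start_s", "activity_index", "phase") %in% names(bins)),
            bin_width_s > 0,
            all(bins$phase %in% c("light", "dark")),
            all(bins$activity_index >= 0))
  out <- structure(as.data.frame(bins),
                   class = c("activity_series", "data.frame"))
  attr(out, "bin_width_s") <- bin_width_s
  out
}

#' Simulate a circadian-modulated home-cage activity series
#'
#' Alternating 12 h light/dark phases (starting in the light phase at time 0)
#' with phase-specific mean activity plus truncated Gaussian noise. Bins are
#' labeled by their start time.
#'
#' @param config A [sim_config()]; `activity_bin_s` sets the bin width.
#' @param dark_mean,light_mean Mean activity index per phase (>= 0, arbitrary
#'   units).
#' @param noise_sd Gaussian noise SD on each bin (values clipped at 0).
#' @param days Number of 24 h days to simulate.
#' @return An [activity_series()].
#' @export
#' @examples
#' s <- simulate_activity_series(sim_config(seed = 1), dark_mean = 3,
#'                               light_mean = 1, noise_sd = 0)
#' relative_amplitude(s)
simulate_activity_series <- function(config, dark_mean = 3, light_mean = 1,
                                     noise_sd = 0.2, days = 7) {
  if (dark_mean < 0 || light_mean < 0) {
    stop("phase means must be >= 0", call. = FALSE)
  }
  set.seed(config$seed + 5L)
  bw <- config$activity_bin_s
  n <- round(days * 86400 / bw)
  start_s <- (seq_len(n) - 1) * bw
  phase <- ifelse((start_s %% 86400) < 43200, "light", "dark")
  mu <- ifelse(phase == "dark", dark_mean, light_mean)
  ai <- pmax(0, mu + rnorm(n, 0, noise_sd))
  activity_series(data.frame(start_s = start_s, activity_index = ai,
                             phase = phase), bin_width_s = bw)
}
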