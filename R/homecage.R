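## Circadian relative amplitude and activity bouts from binned home-cage
## activity-index series.

#' Circadian relative amplitude
#'
#' `RA = (AI_D - AI_L) / (AI_D + AI_L)` where `AI_D` and `AI_L` are the mean
#' activity index over dark-phase and light-phase bins. RA lies in
#' `[-1, 1]` and is invariant to rescaling the activity units.
#'
#' @param series An [activity_series()].
#' @return RA, or `NA` when both phase means are zero (undefined) or a phase
#'   is absent.
#' @export
#' @examples
#' s <- simulate_activity_series(sim_config(seed = 1), dark_mean = 3,
#'                               light_mean = 1, noise_sd = 0)
#' relative_amplitude(s)  # 0.5
relative_amplitude <- function(series) {
  stopifnot(inherits(series, "activity_series"))
  if (!all(c("dark", "light") %in% series$phase)) {
    return(NA_real_)
  }
  ai_d <- mean(series$activity_index[series$phase == "dark"])
  ai_l <- mean(series$activity_index[series$phase == "light"])
  if (ai_d + ai_l == 0) return(NA_real_)
  (ai_d - ai_l) / (ai_d + ai_l)
}

#' Detect activity bouts
#'
#' A bout is a period during which the activity index never falls below
#' `threshold`. Maximal supra-threshold runs of bins are found first;
#' runs separated by sub-threshold gaps shorter than `min_gap_s` are merged;
#' merged runs shorter than `min_duration_s` are then discarded
#' (merge-before-filter). Defaults: threshold 0.2 arbitrary units, 1 min
#' minimum duration, 1 min minimum inter-bout interval.
#'
#' @param series An [activity_series()].
#' @param threshold Activity threshold, arbitrary units.
#' @param min_duration_s Minimum bout duration, seconds.
#' @param min_gap_s Minimum inter-bout interval, seconds.
#' @return Data frame `start_s`, `end_s`, `duration_s` (possibly 0 rows),
#'   with attribute `summary` (`n_bouts`, `mean_duration_s`,
#'   `total_bout_s`).
#' @export
detect_bouts <- function(series, threshold = 0.2, min_duration_s = 60,
                         min_gap_s = 60) {
  stopifnot(inherits(series, "activity_series"))
  bw <- attr(series, "bin_width_s")
  up <- series$activity_index >= threshold
  runs <- rle(up)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  iv <- data.frame(start = starts[runs$values], end = ends[runs$values])
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0))
  if (nrow(iv) == 0) {
    attr(empty, "summary") <- list(n_bouts = 0L, mean_duration_s = NA_real_,
                                   total_bout_s = 0)
    return(empty)
  }
  ## merge runs separated by gaps shorter than min_gap_s
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      gap_bins <- iv$start[i] - merged$end[nrow(merged)] - 1L
      if (gap_bins * bw < min_gap_s) {
        merged$end[nrow(merged)] <- iv$end[i]
      } else {
        merged <- rbind(merged, iv[i, ])
      }
    }
  }
  dur <- (merged$end - merged$start + 1L) * bw
  keep <- dur >= min_duration_s
  out <- data.frame(
    start_s = series$start_s[merged$start[keep]],
    end_s = series$start_s[merged$end[keep]] + bw,
    duration_s = dur[keep]
  )
  attr(out, "summary") <- list(
    n_bouts = nrow(out),
    mean_duration_s = if (nrow(out) > 0) mean(out$duration_s) else NA_real_,
    total_bout_s = sum(out$duration_s)
  )
  out
}

#' Per-animal home-cage metrics report
#'
#' @param series An [activity_series()].
#' @param threshold,min_duration_s,min_gap_s Passed to [detect_bouts()].
#' @return List with `relative_amplitude`, `n_bouts`, `mean_bout_duration_s`,
#'   `total_bout_s`, `mean_activity_dark`, `mean_activity_light`.
#' @export
analyze_homecage <- function(series, threshold = 0.2, min_duration_s = 60,
                             min_gap_s = 60) {
  bouts <- detect_bouts(series, threshold, min_duration_s, min_gap_s)
  s <- attr(bouts, "summary")
  list(
    relative_amplitude = relative_amplitude(series),
    n_bouts = s$n_bouts,
    mean_bout_duration_s = s$mean_duration_s,
    total_bout_s = s$total_bout_s,
    mean_activity_dark = mean(series$activity_index[series$phase == "dark"]),
    mean_activity_light = mean(series$activity_index[series$phase == "light"])
  )
}
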