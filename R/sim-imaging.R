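#' Build a stimulus schedule
#'
#' Draws `n_trials` trial types uniformly from `types` and places their onsets
#' with inter-onset gaps uniform in `config$iti_range`. Stimuli last
#' `config$stim_duration_s` (500 ms by default).
#'
#' @param config A [sim_config()].
#' @param types Trial types to draw from; subset of [trial_types()].
#' @return A `stimulus_schedule`: data frame with columns `trial_index`,
#'   `trial_type`, `onset_s`, `duration_s`, onsets strictly increasing.
#' @export
#' @examples
#' sched <- make_stimulus_schedule(sim_config(seed = 1, n_trials = 12))
#' range(diff(sched$onset_s))
make_stimulus_schedule <- function(config, types = trial_types()) {
  if (length(types) == 0) stop("trial_types must be non-empty", call. = FALSE)
  assert_trial_types(types)
  set.seed(config$seed)
  n <- config$n_trials
  if (n == 0) {
    return(new_stimulus_schedule(data.frame(
      trial_index = integer(0), trial_type = character(0),
      onset_s = numeric(0), duration_s = numeric(0)
    )))
  }
  gaps <- runif(n, config$iti_range[1], config$iti_range[2])
  onsets <- cumsum(gaps)
  drawn <- sample(types, n, replace = TRUE)
  new_stimulus_schedule(data.frame(
    trial_index = seq_len(n), trial_type = drawn,
    onset_s = onsets, duration_s = rep(config$stim_duration_s, n)
  ))
}

new_stimulus_schedule <- function(df) {
  stopifnot(all(c("trial_index", "trial_type", "onset_s", "duration_s")
                %in% names(df)))
  assert_trial_types(unique(df$trial_type))
  if (is.unsorted(df$onset_s, strictly = TRUE) && nrow(df) > 1) {
    stop("schedule onsets must be strictly increasing", call. = FALSE)
  }
  class(df) <- c("stimulus_schedule", "data.frame")
  df
}

#' Generate ground-truth tuning labels for an axon population
#'
#' Assigns each of `config$n_units` simulated axons a true class: a fraction
#' `p_responsive` are stimulus-tuned, the rest are non-responsive. Responsive
#' axons are split between a single-modality closure pattern (`p_unisensory`),
#' a multimodal-only pattern that fires only when at least two of its tuned
#' modalities co-occur (`p_multimodal_only`), and a mixed multisensory pattern
#' tuned to two or three modalities (the remainder).
#'
#' Default class proportions follow the population reported for claustrum
#' axons in cortex: about 47% of axons stimulus-responsive, 4% of responsive
#' axons unisensory, and 35% responsive only to multimodal trial types.
#'
#' @param config A [sim_config()].
#' @param p_responsive Fraction of axons that are stimulus-tuned.
#' @param p_unisensory,p_multimodal_only Within responsive axons, fractions
#'   assigned to the unisensory and multimodal-only patterns.
#' @param respond_prob Per-trial probability that a tuned axon emits a
#'   transient on a matching trial.
#' @return A `ground_truth` data frame, one row per unit: `unit_id`, `label`,
#'   `tuned` (comma-joined modalities), `multimodal_only`, `respond_prob`.
#' @export
make_axon_truth <- function(config, p_responsive = 0.47,
                            p_unisensory = 0.04, p_multimodal_only = 0.35,
                            respond_prob = 0.8) {
  stopifnot(p_unisensory + p_multimodal_only <= 1)
  set.seed(config$seed + 1L)
  n <- config$n_units
  responsive <- runif(n) < p_responsive
  kind <- rep("non_responsive", n)
  u <- runif(n)
  kind[responsive & u < p_unisensory] <- "unisensory"
  kind[responsive & u >= p_unisensory &
         u < p_unisensory + p_multimodal_only] <- "multimodal_only"
  kind[responsive & u >= p_unisensory + p_multimodal_only] <- "mixed"

  tuned <- character(n)
  mm_only <- logical(n)
  label <- character(n)
  for (i in seq_len(n)) {
    if (kind[i] == "non_responsive") {
      tuned[i] <- ""
      label[i] <- "non_responsive"
    } else if (kind[i] == "unisensory") {
      m <- sample(modalities(), 1)
      tuned[i] <- m
      label[i] <- paste0("unisensory:", m)
    } else {
      k <- sample(2:3, 1)
      m <- sort(sample(modalities(), k))
      tuned[i] <- paste(m, collapse = ",")
      if (kind[i] == "multimodal_only") {
        mm_only[i] <- TRUE
        label[i] <- "multisensory:multimodal_only"
      } else {
        label[i] <- "multisensory:mixed"
      }
    }
  }
  structure(data.frame(
    unit_id = seq_len(n), label = label, tuned = tuned,
    multimodal_only = mm_only,
    respond_prob = ifelse(kind == "non_responsive", 0, respond_prob),
    stringsAsFactors = FALSE
  ), class = c("ground_truth", "data.frame"))
}

## trial types on which a unit with the given tuning emits transients
responding_types <- function(tuned_csv, multimodal_only) {
  tuned <- strsplit(tuned_csv, ",", fixed = TRUE)[[1]]
  if (length(tuned) == 0) return(character(0))
  stim <- setdiff(trial_types(), "blank")
  comp <- type_components(stim)
  n_tuned_present <- vapply(comp, function(p) sum(tuned %in% p), integer(1))
  if (multimodal_only) stim[n_tuned_present >= 2] else stim[n_tuned_present >= 1]
}

#' Simulate an axon calcium-imaging recording
#'
#' Generates a ROIs x frames fluorescence matrix at `config$frame_rate`:
#' constant baseline plus per-frame Gaussian noise, plus
#' instantaneous-rise/exponential-decay transients at the onsets of trials
#' matching each unit's tuning (per `truth`), each emitted with probability
#' `respond_prob`. Units flagged multimodal-only fire only when at least two
#' of their tuned modalities co-occur. Blank trials never evoke a transient; a
#' positive `config$spontaneous_rate` injects Poisson-timed spontaneous
#' transients anywhere in the trace. A paired neuropil trace (baseline-only,
#' at half the somatic baseline) is produced per ROI.
#'
#' @param config A [sim_config()].
#' @param schedule A `stimulus_schedule` from [make_stimulus_schedule()].
#' @param truth A `ground_truth` from [make_axon_truth()] with
#'   `nrow == config$n_units`.
#' @param duration_s Recording length, seconds; defaults to the last onset
#'   plus 8 s. Must cover every scheduled trial's analysis window.
#' @return An [axon_recording()] object.
#' @export
simulate_axon_population <- function(config, schedule, truth,
                                     duration_s = NULL) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  if (nrow(truth) != config$n_units) {
    stop("truth must have one row per configured unit", call. = FALSE)
  }
  need <- if (nrow(schedule) > 0) max(schedule$onset_s) + 8 else 10
  if (is.null(duration_s)) duration_s <- need
  if (duration_s < need) {
    stop("schedule extends past the recording length", call. = FALSE)
  }
  set.seed(config$seed + 2L)
  fr <- config$frame_rate
  n_frames <- ceiling(duration_s * fr)
  t_frame <- (seq_len(n_frames) - 1) / fr
  n <- config$n_units

  fluo <- matrix(rnorm(n * n_frames, config$baseline, config$noise_sd),
                 nrow = n, ncol = n_frames)
  neu <- matrix(rnorm(n * n_frames, config$baseline / 2, config$noise_sd / 2),
                nrow = n, ncol = n_frames)

  add_transient <- function(row, t0) {
    idx <- which(t_frame >= t0)
    if (length(idx) == 0) return(row)
    row[idx] <- row[idx] +
      config$transient_amplitude * exp(-(t_frame[idx] - t0) / config$transient_decay)
    row
  }

  for (i in seq_len(n)) {
    types_i <- responding_types(truth$tuned[i], truth$multimodal_only[i])
    hits <- schedule$trial_type %in% types_i
    if (any(hits)) {
      fire <- runif(sum(hits)) < truth$respond_prob[i]
      for (t0 in schedule$onset_s[hits][fire]) {
        fluo[i, ] <- add_transient(fluo[i, ], t0)
      }
    }
    if (config$spontaneous_rate > 0) {
      n_spont <- rpois(1, config$spontaneous_rate * duration_s)
      if (n_spont > 0) {
        for (t0 in runif(n_spont, 0, duration_s)) {
          fluo[i, ] <- add_transient(fluo[i, ], t0)
        }
      }
    }
  }
  axon_recording(fluo, neuropil = neu, frame_rate = fr, schedule = schedule)
}

#' Construct an axon recording container
#'
#' @param fluorescence ROIs x frames matrix, arbitrary fluorescence units.
#' @param neuropil Matching ROIs x frames neuropil matrix, or `NULL`.
#' @param frame_rate Frames per second (> 0).
#' @param schedule A `stimulus_schedule`; onsets must fall inside the
#'   recording.
#' @return An `axon_recording` object.
#' @export
axon_recording <- function(fluorescence, neuropil = NULL, frame_rate,
                           schedule) {
  stopifnot(is.matrix(fluorescence), frame_rate > 0)
  if (!is.null(neuropil)) stopifnot(identical(dim(neuropil), dim(fluorescence)))
  stopifnot(inherits(schedule, "stimulus_schedule"))
  dur <- ncol(fluorescence) / frame_rate
  if (nrow(schedule) > 0 && max(schedule$onset_s) > dur) {
    stop("schedule onsets extend past the recording", call. = FALSE)
  }
  structure(list(fluorescence = fluorescence, neuropil = neuropil,
                 frame_rate = frame_rate, schedule = schedule),
            class = "axon_recording")
}

#' @export
print.axon_recording <- function(x, ...) {
  cat("<axon_recording> ", nrow(x$fluorescence), " ROIs x ",
      ncol(x$fluorescence), " frames @ ", x$frame_rate, " Hz, ",
      nrow(x$schedule), " trials",
      if (is.null(x$neuropil)) ", no neuropil" else ", with neuropil",
      "\n", sep = "")
  invisible(x)
}
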