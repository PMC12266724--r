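## dF/F computation, responsiveness testing, and the uni-/multisensory
## taxonomy for axonal two-photon calcium imaging.

#' Compute dF/F per ROI
#'
#' When a neuropil matrix is present the trace is first corrected as
#' `F - coefficient * FNeu` (coefficient 0.7). dF/F is then
#' `(F - Fbar) / Fbar` with `Fbar` the temporal mean of the corrected trace
#' over the whole session, per ROI. ROIs whose corrected mean is not positive
#' are degenerate: their rows are set to `NA` and recorded in the
#' `"excluded"` attribute.
#'
#' @param recording An [axon_recording()], or a ROIs x frames matrix.
#' @param neuropil_coefficient Neuropil subtraction factor (0.7).
#' @return ROIs x frames matrix of dF/F, with attribute `excluded` (integer
#'   ROI indices dropped for non-positive mean).
#' @export
#' @examples
#' sched <- make_stimulus_schedule(sim_config(n_trials = 0))
#' rec <- axon_recording(matrix(c(1, 1, 2), 1), frame_rate = 30,
#'                       schedule = sched)
#' compute_dff(rec)  # -0.25 -0.25 0.5
compute_dff <- function(recording, neuropil_coefficient = 0.7) {
  if (inherits(recording, "axon_recording")) {
    f <- recording$fluorescence
    neu <- recording$neuropil
  } else {
    f <- recording
    neu <- NULL
  }
  stopifnot(is.matrix(f))
  if (!is.null(neu)) f <- f - neuropil_coefficient * neu
  fbar <- rowMeans(f)
  bad <- which(!(fbar > 0))
  dff <- (f - fbar) / fbar
  if (length(bad) > 0) {
    dff[bad, ] <- NA_real_
    message(length(bad), " ROI(s) excluded: non-positive mean fluorescence")
  }
  attr(dff, "excluded") <- bad
  dff
}

#' Extract aligned per-trial windows
#'
#' Cuts each trial's segment from `pre_s` before to `post_s` after stimulus
#' onset (half-open: the first frame at or after onset starts the
#' post-stimulus period). Trials whose window is not fully inside the
#' recording are dropped and listed in the `dropped` element.
#'
#' @param dff ROIs x frames dF/F matrix (see [compute_dff()]).
#' @param schedule A `stimulus_schedule`.
#' @param frame_rate Frames per second.
#' @param pre_s,post_s Window extent around onset, seconds (2 and 6).
#' @return A `trial_windows` object: list with `segments` (axons x trials x
#'   frames array), `trial_type`, `pre_frames`, `frame_rate`, `dropped`
#'   (trial indices), and `type_average()`-style per-type mean traces via
#'   `attr(, "by_type")` accessor [type_averages()].
#' @export
trial_windows <- function(dff, schedule, frame_rate, pre_s = 2, post_s = 6) {
  stopifnot(is.matrix(dff), frame_rate > 0)
  pre_f <- round(pre_s * frame_rate)
  post_f <- round(post_s * frame_rate)
  n_frames <- ncol(dff)
  ## first frame at or after onset (frame i spans time (i-1)/rate)
  onset_idx <- ceiling(schedule$onset_s * frame_rate - 1e-9) + 1L
  lo <- onset_idx - pre_f
  hi <- onset_idx + post_f - 1L
  keep <- lo >= 1L & hi <= n_frames
  dropped <- schedule$trial_index[!keep]
  if (length(dropped) > 0) {
    message(length(dropped), " edge trial(s) dropped from windowing")
  }
  n_keep <- sum(keep)
  seg <- array(NA_real_, dim = c(nrow(dff), n_keep, pre_f + post_f))
  ki <- which(keep)
  for (j in seq_len(n_keep)) {
    seg[, j, ] <- dff[, lo[ki[j]]:hi[ki[j]], drop = FALSE]
  }
  structure(list(segments = seg,
                 trial_type = schedule$trial_type[keep],
                 pre_frames = pre_f, frame_rate = frame_rate,
                 dropped = dropped),
            class = "trial_windows")
}

#' Per-trial-type average traces
#'
#' @param tw A [trial_windows()] object.
#' @return Named list (one per trial type present) of axons x frames mean
#'   traces.
#' @export
type_averages <- function(tw) {
  stopifnot(inherits(tw, "trial_windows"))
  out <- list()
  for (ty in unique(tw$trial_type)) {
    idx <- which(tw$trial_type == ty)
    out[[ty]] <- apply(tw$segments[, idx, , drop = FALSE], c(1, 3), mean)
  }
  out
}

## per-trial scalar summaries: mean dF/F over the 1 s pre and post windows
pre_post_means <- function(tw) {
  fr <- tw$frame_rate
  pre_idx <- (tw$pre_frames - fr + 1):tw$pre_frames
  post_idx <- (tw$pre_frames + 1):(tw$pre_frames + fr)
  list(pre = apply(tw$segments[, , pre_idx, drop = FALSE], c(1, 2), mean),
       post = apply(tw$segments[, , post_idx, drop = FALSE], c(1, 2), mean))
}

#' Stimulus responsiveness per axon and trial type
#'
#' For each (axon, trial type) pair, compares the mean dF/F in the second
#' before stimulus onset with the second after, across that type's trials,
#' using a two-sided Mann–Whitney U test. The p-values of every testable pair
#' in the dataset form one family corrected by Benjamini–Hochberg FDR at
#' `alpha` (1%). Types with fewer than `min_trials` complete trials are
#' untestable and excluded from the family.
#'
#' @param tw A [trial_windows()] object.
#' @param alpha BH false-discovery level (0.01).
#' @param min_trials Minimum trials per type for testing (3).
#' @return A `responsiveness` object: list with `p`, `p_adj` (axons x types
#'   matrices), `responsive` (logical matrix), and `responsive_types` (list of
#'   character vectors per axon).
#' @export
responsiveness_test <- function(tw, alpha = 0.01, min_trials = 3) {
  stopifnot(inherits(tw, "trial_windows"))
  mm <- pre_post_means(tw)
  types <- intersect(trial_types(), unique(tw$trial_type))
  n_axon <- dim(tw$segments)[1]
  p <- matrix(NA_real_, n_axon, length(types),
              dimnames = list(NULL, types))
  for (ty in types) {
    idx <- which(tw$trial_type == ty)
    if (length(idx) < min_trials) next
    for (a in seq_len(n_axon)) {
      pre <- mm$pre[a, idx]
      post <- mm$post[a, idx]
      if (anyNA(pre) || anyNA(post)) next
      p[a, ty] <- mw_p(pre, post)
    }
  }
  p_adj <- p
  p_adj[] <- stats::p.adjust(p, method = "BH")
  responsive <- !is.na(p_adj) & p_adj <= alpha
  structure(list(
    p = p, p_adj = p_adj, responsive = responsive,
    responsive_types = apply(responsive, 1, function(r) types[r],
                             simplify = FALSE)
  ), class = "responsiveness")
}

#' Uni-/multisensory taxonomy of a response pattern
#'
#' Classifies the set of trial types an axon responds to. An axon is
#' *unisensory* when there is exactly one modality m such that it responds to
#' every trial type containing m and to no other type — i.e. its response is
#' not modulated by added modalities. Any other non-empty pattern over the
#' seven stimulus-containing types is *multisensory*: responding to several
#' modalities, to multimodal types only, or responding to a unimodal type but
#' losing (or gaining) the response when modalities are added. The modal
#' category records whether the responsive types are exclusively multimodal,
#' exclusively unimodal, or mixed. Blank trials are ignored here and reported
#' separately by [analyze_axons()].
#'
#' @param responsive_types Character vector of trial-type labels.
#' @return List with `sensory_class` (`"non_responsive"`, `"unisensory"`,
#'   `"multisensory"`) and `modal_category` (`"none"`,
#'   `"exclusively_unimodal"`, `"exclusively_multimodal"`, `"mixed"`).
#' @export
#' @examples
#' classify_sensory(c("sound", "sound+light", "sound+whisker",
#'                    "sound+light+whisker"))  # unisensory
#' classify_sensory("sound+light")             # multisensory, excl. multimodal
classify_sensory <- function(responsive_types) {
  assert_trial_types(responsive_types)
  st <- setdiff(responsive_types, "blank")
  if (length(st) == 0) {
    return(list(sensory_class = "non_responsive", modal_category = "none"))
  }
  stim <- setdiff(trial_types(), "blank")
  uni <- FALSE
  for (m in modalities()) {
    closure <- stim[type_contains(stim, m)]
    if (setequal(st, closure)) {
      uni <- TRUE
      break
    }
  }
  arity <- type_arity(st)
  modal_category <- if (all(arity >= 2)) "exclusively_multimodal"
                    else if (all(arity == 1)) "exclusively_unimodal"
                    else "mixed"
  list(sensory_class = if (uni) "unisensory" else "multisensory",
       modal_category = modal_category)
}

#' Trial-wise response probability from AUC thresholding
#'
#' For every trial the response AUC is the trapezoidal integral of dF/F over
#' the second after stimulus onset, after subtracting that trial's mean dF/F
#' over the second before onset (trial-by-trial baselining). A presentation
#' evokes a response when its AUC exceeds the pooled mean + 1 SD of the AUCs
#' of all axons and all trials in the dataset. Response probability is the
#' fraction of a type's presentations that evoke a response, per axon.
#'
#' @param tw A [trial_windows()] object.
#' @param threshold Optional fixed AUC threshold; default pools mean + 1 SD
#'   over the whole dataset.
#' @return List with `auc` (axons x trials), `threshold`, `responding`
#'   (logical axons x trials), and `probability` (axons x types matrix, `NA`
#'   for types with no trials).
#' @export
trial_response_probability <- function(tw, threshold = NULL) {
  stopifnot(inherits(tw, "trial_windows"))
  fr <- tw$frame_rate
  pre_idx <- (tw$pre_frames - fr + 1):tw$pre_frames
  post_idx <- (tw$pre_frames + 1):(tw$pre_frames + fr)
  t_post <- (seq_along(post_idx) - 1) / fr
  base <- apply(tw$segments[, , pre_idx, drop = FALSE], c(1, 2), mean)
  n_axon <- dim(tw$segments)[1]
  n_trial <- dim(tw$segments)[2]
  auc <- matrix(NA_real_, n_axon, n_trial)
  for (a in seq_len(n_axon)) {
    for (j in seq_len(n_trial)) {
      auc[a, j] <- pracma::trapz(t_post,
                                 tw$segments[a, j, post_idx] - base[a, j])
    }
  }
  if (is.null(threshold)) {
    threshold <- mean(auc, na.rm = TRUE) + stats::sd(as.vector(auc),
                                                     na.rm = TRUE)
  }
  responding <- !is.na(auc) & auc > threshold
  types <- intersect(trial_types(), unique(tw$trial_type))
  probability <- matrix(NA_real_, n_axon, length(types),
                        dimnames = list(NULL, types))
  for (ty in types) {
    idx <- which(tw$trial_type == ty)
    if (length(idx) == 0) next
    probability[, ty] <- rowMeans(responding[, idx, drop = FALSE])
  }
  list(auc = auc, threshold = threshold, responding = responding,
       probability = probability)
}

#' Population-level tests on response probabilities
#'
#' Kruskal–Wallis test of response probability (or magnitude) across trial
#' types, and the Pearson correlation between session index and session-mean
#' response probability (stability across experimental sessions).
#'
#' @param probability Axons x types matrix (e.g. from
#'   [trial_response_probability()]).
#' @param session_index,session_means Optional paired vectors of session
#'   number and per-session mean response probability.
#' @return List with `kruskal` (`H`, `df`, `p`; `NA` when fewer than two
#'   groups are available) and `pearson` (`r`, `p`; `r` is `NA` when either
#'   vector has zero variance).
#' @export
population_tests <- function(probability, session_index = NULL,
                             session_means = NULL) {
  groups <- list()
  for (ty in colnames(probability)) {
    v <- probability[, ty]
    v <- v[!is.na(v)]
    if (length(v) > 0) groups[[ty]] <- v
  }
  kr <- list(H = NA_real_, df = NA_real_, p = NA_real_)
  if (length(groups) >= 2) {
    kt <- stats::kruskal.test(groups)
    kr <- list(H = unname(kt$statistic), df = unname(kt$parameter),
               p = kt$p.value)
  }
  pe <- list(r = NA_real_, p = NA_real_)
  if (!is.null(session_index) && !is.null(session_means)) {
    if (stats::sd(session_index) > 0 && stats::sd(session_means) > 0) {
      ct <- stats::cor.test(session_index, session_means)
      pe <- list(r = unname(ct$estimate), p = ct$p.value)
    }
  }
  list(kruskal = kr, pearson = pe)
}

#' Full axon-imaging analysis
#'
#' Runs the imaging pipeline on one recording: dF/F (with 0.7 neuropil
#' correction), trial windowing (-2 s to +6 s), Mann–Whitney responsiveness
#' with BH FDR at `alpha`, the uni-/multisensory taxonomy, and AUC-threshold
#' response probabilities. Blank-trial responsiveness is reported in its own
#' column and never enters the taxonomy.
#'
#' @param recording An [axon_recording()].
#' @param alpha BH level for responsiveness (0.01).
#' @param neuropil_coefficient Passed to [compute_dff()].
#' @param auc_threshold Optional fixed AUC threshold (e.g. pooled across a
#'   multi-recording cohort); defaults to this recording's pool.
#' @return An `axon_profiles` object: data frame with one row per axon
#'   (`axon_id`, `sensory_class`, `modal_category`, `responsive_types`,
#'   `blank_responsive`, `prob_<type>` columns) plus attributes
#'   `responsiveness`, `response_probability`, `population`.
#' @export
analyze_axons <- function(recording, alpha = 0.01, neuropil_coefficient = 0.7,
                          auc_threshold = NULL) {
  dff <- compute_dff(recording, neuropil_coefficient)
  tw <- trial_windows(dff, recording$schedule, recording$frame_rate)
  resp <- responsiveness_test(tw, alpha = alpha)
  rp <- trial_response_probability(tw, threshold = auc_threshold)
  n_axon <- nrow(dff)
  cls <- lapply(resp$responsive_types, classify_sensory)
  prof <- data.frame(
    axon_id = seq_len(n_axon),
    sensory_class = vapply(cls, `[[`, character(1), "sensory_class"),
    modal_category = vapply(cls, `[[`, character(1), "modal_category"),
    responsive_types = vapply(resp$responsive_types, function(x) {
      paste(setdiff(x, "blank"), collapse = ";")
    }, character(1)),
    blank_responsive = vapply(resp$responsive_types, function(x) {
      "blank" %in% x
    }, logical(1))
  )
  pm <- rp$probability
  colnames(pm) <- paste0("prob_", gsub("+", "_", colnames(pm), fixed = TRUE))
  prof <- cbind(prof, as.data.frame(pm))
  structure(prof,
            class = c("axon_profiles", "data.frame"),
            responsiveness = resp,
            response_probability = rp,
            population = population_tests(rp$probability))
}

#' @export
print.axon_profiles <- function(x, ...) {
  cat("<axon_profiles> ", nrow(x), " axons: ",
      sum(x$sensory_class != "non_responsive"), " responsive (",
      sum(x$sensory_class == "unisensory"), " unisensory, ",
      sum(x$sensory_class == "multisensory"), " multisensory)\n", sep = "")
  NextMethod()
}
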